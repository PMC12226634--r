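# Independent simulation of the persistence rule on a sequence of per-frame
# class sets: reference starts as the frame-0 set, a trigger fires after
# nT + 1 consecutive discrepant frames (first full window after the previous
# trigger), whereupon the reference becomes the set at the back-track frame
# and the run restarts. Used to cross-check orchestrator trigger counts.
simulateTriggers <- function(sets, nT) {
  ref <- sets[[1]]
  triggers <- data.frame(tPrime = integer(0), backtrack = integer(0))
  runStart <- NA_integer_
  t <- 1L
  while (t <= length(sets) - 1L) {
    discrepant <- !identical(sets[[t + 1L]], ref)
    if (!discrepant) runStart <- NA_integer_
    else if (is.na(runStart)) runStart <- t
    if (!is.na(runStart) && t - runStart == nT) {
      b <- t - nT
      triggers <- rbind(triggers, data.frame(tPrime = t, backtrack = b))
      ref <- sets[[b + 1L]]
      runStart <- NA_integer_
    }
    t <- t + 1L
  }
  triggers
}
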