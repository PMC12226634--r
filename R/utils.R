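# Internal helpers shared across modules.

# Round half away from zero, the rounding rule used for flow displacements.
rhalf <- function(x) sign(x) * floor(abs(x) + 0.5)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never disturbs user
# simulations.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# FNV-1a 32-bit hash over a raw vector; used for config fingerprints in run
# manifests. Multiplication is split into 16-bit halves to stay within double
# precision.
fnv1a32 <- function(raw) {
  h <- 2166136261
  m <- 16777619
  for (b in as.integer(raw)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * m) %% 65536) * 65536 + h0 * m) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# 8-connected component labelling of a binary matrix. EBImage::bwlabel is
# 4-connected, so labels touching diagonally are merged with union-find and
# the result is relabelled 1..K in row-major first-pixel order (deterministic
# component ordering for anchor sampling and detections).
labelComponents8 <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(EBImage::bwlabel(m)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n > 1L) {
    H <- nrow(lab); W <- ncol(lab)
    a1 <- lab[-H, -W]; b1 <- lab[-1, -1]   # (r,c) ~ (r+1,c+1)
    a2 <- lab[-1, -W]; b2 <- lab[-H, -1]   # (r+1,c) ~ (r,c+1)
    prs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
    prs <- prs[prs[, 1] > 0L & prs[, 2] > 0L & prs[, 1] != prs[, 2], ,
               drop = FALSE]
    if (nrow(prs)) {
      prs <- unique(prs)
      parent <- seq_len(n)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (k in seq_len(nrow(prs))) {
        ra <- find(prs[k, 1]); rb <- find(prs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(n), find, integer(1))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  relabelRowMajor(lab)
}

relabelRowMajor <- function(lab) {
  pos <- which(lab > 0L)
  if (!length(pos)) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  r <- ((pos - 1L) %% H)
  cc <- ((pos - 1L) %/% H)
  key <- r * W + cc                      # row-major scan index, 0-based
  firsts <- tapply(key, lab[pos], min)
  ord <- order(firsts)
  newid <- integer(max(lab))
  newid[as.integer(names(firsts))[ord]] <- seq_along(ord)
  lab[pos] <- newid[lab[pos]]
  lab
}

# Euclidean distance to the nearest non-foreground pixel, with the frame
# border counting as boundary (EBImage::distmap extends foreground beyond the
# edge, so the image is zero-padded first).
interiorDistance <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- as.numeric(mask != 0)
  d <- matrix(as.numeric(EBImage::distmap(pad)), H + 2L, W + 2L)
  d[2:(H + 1L), 2:(W + 1L), drop = FALSE]
}

# Positions (matrix pos x {row,col}, 1-based) of 8-neighbourhood local maxima
# of `d` restricted to `mask`.
localMaxima8 <- function(d, mask) {
  H <- nrow(d); W <- ncol(d)
  pd <- matrix(-Inf, H + 2L, W + 2L)
  pd[2:(H + 1L), 2:(W + 1L)] <- ifelse(mask != 0, d, -Inf)
  ctr <- pd[2:(H + 1L), 2:(W + 1L), drop = FALSE]
  ok <- matrix(TRUE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pd[(2:(H + 1L)) + dr, (2:(W + 1L)) + dc, drop = FALSE]
    ok <- ok & (ctr >= nb)
  }
  which(ok & (mask != 0) & is.finite(ctr), arr.ind = TRUE)
}

# Order positions by row-major scan (row, then col); pos is 1-based (r, c).
orderRowMajor <- function(r, c) order(r, c)

classSetLabel <- function(x) paste(sort(unique(as.integer(x))), collapse = ",")

stopShape <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
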