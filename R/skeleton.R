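# Binary thinning (Guo-Hall)
# ------------------------------------------------------------------
# Reduces a vessel band to a 1-px-wide 8-connected centerline. Guo-Hall's
# two-subiteration scheme is used because it thins diagonal bands cleanly
# (Zhang-Suen-style schemes leave deletion-invariant 2-px staircases on
# some diagonals). Vectorized over the whole image via shifted copies of
# the matrix; a sequential simple-point pass then removes any residual
# thick spots.

# out[i, j] = m[i + dr, j + dc], out-of-bounds filled with 0
.shift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

#' Skeletonize a binary mask
#'
#' Guo-Hall thinning: iteratively deletes contour pixels whose removal
#' preserves local connectivity until the shape is a one-pixel-wide
#' centerline.
#'
#' @param mask binary matrix (nonzero = foreground).
#' @return logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (step in 0:1) {
      # neighbors clockwise from north: p2..p9
      p2 <- .shift(m, -1L,  0L); p3 <- .shift(m, -1L,  1L)
      p4 <- .shift(m,  0L,  1L); p5 <- .shift(m,  1L,  1L)
      p6 <- .shift(m,  1L,  0L); p7 <- .shift(m,  1L, -1L)
      p8 <- .shift(m,  0L, -1L); p9 <- .shift(m, -1L, -1L)
      cn <- ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
            ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2))
      n1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      n2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      nn <- pmin(n1, n2)
      m3 <- if (step == 0L) ((p2 | p3 | (!p5)) & p4) == 0 else
                            ((p6 | p7 | (!p9)) & p8) == 0
      del <- m == 1L & cn == 1 & nn >= 2 & nn <= 3 & m3
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  .post_thin(m == 1L)
}

# sequential cleanup: remove remaining simple pixels (crossing number 1,
# not an endpoint) one at a time until the skeleton is strictly 1 px wide
.post_thin <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  nb_off <- cbind(c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
                  c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))
  repeat {
    changed <- FALSE
    px <- which(sk, arr.ind = TRUE)
    for (i in seq_len(nrow(px))) {
      r <- px[i, 1]; c <- px[i, 2]
      if (!sk[r, c]) next
      rs <- r + nb_off[, 1]; cs <- c + nb_off[, 2]
      inb <- rs >= 1L & rs <= nr & cs >= 1L & cs <= nc
      v <- logical(8); v[inb] <- sk[cbind(rs[inb], cs[inb])]
      b <- sum(v)
      if (b < 3L || b > 6L) next
      vv <- c(v, v[1])
      a <- sum(!vv[-9] & vv[-1])
      if (a == 1L) {
        sk[r, c] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sk
}

# number of 8-connected skeleton neighbors of each pixel
.neighbor_count <- function(sk) {
  m <- matrix(as.integer(sk), nrow(sk), ncol(sk))
  .shift(m, -1L, 0L) + .shift(m, -1L, 1L) + .shift(m, 0L, 1L) +
    .shift(m, 1L, 1L) + .shift(m, 1L, 0L) + .shift(m, 1L, -1L) +
    .shift(m, 0L, -1L) + .shift(m, -1L, -1L)
}
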