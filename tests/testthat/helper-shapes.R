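# Shared fixture builders: all fixtures are generated in code.

# stamp a constant-width band around continuous centerline points
draw_band <- function(mask, pts, width, code = 1L) {
  rad <- width / 2
  g <- ceiling(rad)
  offs <- expand.grid(dr = -g:g, dc = -g:g)
  n <- nrow(pts); m <- nrow(offs)
  pr <- rep(pts[, 1], each = m); pc <- rep(pts[, 2], each = m)
  rr <- round(pr) + rep(offs$dr, n); cc <- round(pc) + rep(offs$dc, n)
  keep <- (rr - pr)^2 + (cc - pc)^2 < rad^2 &
    rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
  mask[cbind(rr[keep], cc[keep])] <- code
  mask
}

# horizontal strip of given height (odd), axis at `row`
strip_mask <- function(h = 60, w = 120, row = 30, height = 7,
                       cols = 10:109, code = 1L) {
  m <- matrix(0L, h, w)
  half <- (height - 1L) %/% 2L
  m[(row - half):(row + half), cols] <- code
  m
}

# Y junction: horizontal stem, two straight daughters at +-35 degrees
y_mask <- function(stem_w = 9, d1_w = 7, d2_w = 5) {
  mk <- matrix(0L, 200, 260)
  t1 <- seq(0, 120, by = 0.25)
  mk <- draw_band(mk, cbind(100, 20 + t1), stem_w)
  for (a in c(-35, 35)) {
    th <- a * pi / 180
    t2 <- seq(0, 90, by = 0.25)
    w <- if (a < 0) d1_w else d2_w
    mk <- draw_band(mk, cbind(100 + t2 * sin(th), 140 + t2 * cos(th)), w)
  }
  mk
}

# minimal report carrying just the differentiator parameters
fake_report <- function(crae = 15, avr = 0.8, mean_artery_width = 8) {
  structure(list(
    caliber = list(crae = crae, crve = crae / avr, avr = avr, zone = "B"),
    per_class = list(
      artery = list(zones = list(all = list(mean_width = mean_artery_width))),
      vein = list(zones = list(all = list(mean_width = mean_artery_width * 1.2)))),
    fractal_dimension = 1.4, flags = character(0)),
    class = "morphometry_report")
}

# a junction literal
jn <- function(r0, daughters) {
  structure(list(position = c(0, 0), r0 = r0,
                 daughters = sort(daughters, decreasing = TRUE),
                 node_id = 1L), class = "junction")
}

# hand-built vessel graph: straight pixel chains (for tree path stats)
toy_tree_graph <- function() {
  chain <- function(p1, p2) {
    n <- max(abs(p2 - p1)) + 1L
    cbind(round(seq(p1[1], p2[1], length.out = n)),
          round(seq(p1[2], p2[2], length.out = n)))
  }
  nodes <- data.frame(id = 1:4,
                      row = c(1, 1, 1, 8), col = c(1, 11, 16, 11),
                      degree = c(1L, 3L, 1L, 1L))
  edges <- list(
    list(from = 1L, to = 2L, pixels = chain(c(1, 1), c(1, 11))),   # length 10
    list(from = 2L, to = 3L, pixels = chain(c(1, 11), c(1, 16))),  # length 5
    list(from = 2L, to = 4L, pixels = chain(c(1, 11), c(8, 11))))  # length 7
  structure(list(nodes = nodes, edges = edges, vessel_class = "artery",
                 skeleton = NULL, flags = character(0)),
            class = "vessel_graph")
}
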