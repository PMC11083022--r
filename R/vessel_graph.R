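# Vessel graph extraction
# ------------------------------------------------------------------
# From an artery/vein label mask, one vessel class at a time:
#   * skeletonize the class's pixels to a 1-px centerline,
#   * nodes = skeleton pixels with != 2 neighbors (endpoints, junctions),
#     adjacent node pixels clustered into a single node,
#   * edges = maximal 8-connected chains between nodes,
#   * spurs (terminal edges shorter than min_spur_px) pruned iteratively.
# Widths are then profiled along each edge by cross-sectional ray search.

.class_code <- function(vessel_class) {
  if (is.numeric(vessel_class)) return(as.integer(vessel_class))
  switch(match.arg(vessel_class, c("artery", "vein")), artery = 1L, vein = 2L)
}

.N8 <- cbind(dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
             dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))

# cluster 8-adjacent node pixels (BFS over the, typically few, node pixels)
.cluster_pixels <- function(pix) {
  n <- nrow(pix)
  if (n == 0L) return(integer(0))
  key <- paste(pix[, 1], pix[, 2])
  lookup <- setNames(seq_len(n), key)
  lab <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (lab[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      nb <- cbind(pix[p, 1] + .N8[, 1], pix[p, 2] + .N8[, 2])
      hit <- lookup[paste(nb[, 1], nb[, 2])]
      hit <- hit[!is.na(hit)]
      new <- hit[lab[hit] == 0L]
      lab[new] <- cur
      queue <- c(queue, new)
    }
  }
  lab
}

# trace nodes and edges from a skeleton; returns list(nodes, edges)
.trace_graph <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  ncount <- .neighbor_count(sk)
  node_px <- which(sk & ncount != 2L, arr.ind = TRUE)
  nodemap <- matrix(0L, nr, nc)
  clab <- .cluster_pixels(node_px)
  n_nodes <- if (length(clab)) max(clab) else 0L
  if (nrow(node_px)) nodemap[node_px] <- clab
  edges <- list()
  visited <- matrix(FALSE, nr, nc)          # interior (non-node) pixels consumed
  add_edge <- function(pix, from, to) {
    edges[[length(edges) + 1L]] <<- list(from = from, to = to, pixels = pix)
  }
  sk_at <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && sk[r, c]
  if (nrow(node_px)) {
    seen_pair <- character(0)
    for (i in seq_len(nrow(node_px))) {
      p <- node_px[i, ]
      for (k in seq_len(8L)) {
        q <- c(p[1] + .N8[k, 1], p[2] + .N8[k, 2])
        if (!sk_at(q[1], q[2])) next
        qn <- nodemap[q[1], q[2]]
        if (qn > 0L) {
          # direct node-to-node contact between different clusters
          if (qn != clab[i]) {
            key <- paste(min(clab[i], qn), max(clab[i], qn),
                         min(p[1], q[1]), min(p[2], q[2]))
            if (!(key %in% seen_pair)) {
              seen_pair <- c(seen_pair, key)
              add_edge(rbind(p, q), clab[i], qn)
            }
          }
          next
        }
        if (visited[q[1], q[2]]) next
        # walk the chain of degree-2 pixels until the next node pixel
        chain <- list(p, q)
        visited[q[1], q[2]] <- TRUE
        prev <- p; cur <- q; to <- NA_integer_
        repeat {
          nb <- cbind(cur[1] + .N8[, 1], cur[2] + .N8[, 2])
          ok <- nb[, 1] >= 1L & nb[, 1] <= nr & nb[, 2] >= 1L & nb[, 2] <= nc
          ok[ok] <- sk[nb[ok, , drop = FALSE]]
          cand <- nb[ok & !(nb[, 1] == prev[1] & nb[, 2] == prev[2]), ,
                     drop = FALSE]
          if (nrow(cand) == 0L) { to <- 0L; break }      # dead end (shouldn't)
          # prefer a node pixel if one is adjacent
          cn <- nodemap[cand]
          j <- if (any(cn > 0L)) which(cn > 0L)[1] else 1L
          nxt <- cand[j, ]
          chain[[length(chain) + 1L]] <- nxt
          if (nodemap[nxt[1], nxt[2]] > 0L) { to <- nodemap[nxt[1], nxt[2]]; break }
          visited[nxt[1], nxt[2]] <- TRUE
          prev <- cur; cur <- nxt
        }
        if (is.na(to) || to == 0L) to <- clab[i]          # degenerate; close on self
        add_edge(do.call(rbind, chain), clab[i], to)
      }
    }
    # every open chain is traced from both of its end nodes; keep one copy
    if (length(edges) > 1L) {
      sig <- vapply(edges, function(e) {
        px <- e$pixels
        a <- paste(px[1, ], collapse = ","); b <- paste(px[nrow(px), ], collapse = ",")
        paste(min(a, b), max(a, b), nrow(px))
      }, character(1))
      edges <- edges[!duplicated(sig)]
    }
  }
  # isolated cycles: skeleton pixels with exactly 2 neighbors, never visited
  rest <- which(sk & ncount == 2L & !visited & nodemap == 0L, arr.ind = TRUE)
  restmap <- matrix(FALSE, nr, nc); if (nrow(rest)) restmap[rest] <- TRUE
  while (any(restmap)) {
    start <- which(restmap, arr.ind = TRUE)[1, ]
    n_nodes <- n_nodes + 1L
    node_px <- rbind(node_px, matrix(start, 1L)); clab <- c(clab, n_nodes)
    nodemap[start[1], start[2]] <- n_nodes
    restmap[start[1], start[2]] <- FALSE
    chain <- list(start); prev <- start; cur <- start
    repeat {
      nb <- cbind(cur[1] + .N8[, 1], cur[2] + .N8[, 2])
      ok <- nb[, 1] >= 1L & nb[, 1] <= nr & nb[, 2] >= 1L & nb[, 2] <= nc
      ok[ok] <- restmap[nb[ok, , drop = FALSE]]
      cand <- nb[ok, , drop = FALSE]
      if (nrow(cand) == 0L) break
      nxt <- cand[1, ]
      restmap[nxt[1], nxt[2]] <- FALSE
      chain[[length(chain) + 1L]] <- nxt
      prev <- cur; cur <- nxt
    }
    chain[[length(chain) + 1L]] <- start                  # close the loop
    edges[[length(edges) + 1L]] <- list(from = n_nodes, to = n_nodes,
                                        pixels = do.call(rbind, chain))
  }
  # contract pass-through nodes (exactly two incident chains): staircase
  # corners detected as nodes would otherwise fragment segments
  contracted <- integer(0)
  repeat {
    if (length(edges) < 2L || n_nodes == 0L) break
    deg <- integer(n_nodes)
    for (e in edges) {
      deg[e$from] <- deg[e$from] + 1L
      deg[e$to] <- deg[e$to] + 1L
    }
    cand <- NULL
    for (n in setdiff(which(deg == 2L), contracted)) {
      inc <- which(vapply(edges, function(e)
        xor(e$from == n, e$to == n), logical(1)))
      if (length(inc) == 2L) { cand <- c(n, inc); break }
    }
    if (is.null(cand)) break
    n <- cand[1]; e1 <- edges[[cand[2]]]; e2 <- edges[[cand[3]]]
    p1 <- e1$pixels; if (e1$from == n) { p1 <- p1[nrow(p1):1, , drop = FALSE] }
    p2 <- e2$pixels; if (e2$to == n) { p2 <- p2[nrow(p2):1, , drop = FALSE] }
    if (all(p1[nrow(p1), ] == p2[1, ])) p2 <- p2[-1, , drop = FALSE]
    merged <- list(from = if (e1$from == n) e1$to else e1$from,
                   to = if (e2$to == n) e2$from else e2$to,
                   pixels = rbind(p1, p2))
    edges <- c(edges[-cand[2:3]], list(merged))
    contracted <- c(contracted, n)
  }
  # node table: cluster centroids and degrees
  if (n_nodes > 0L) {
    rows <- tapply(node_px[, 1], clab, mean)
    cols <- tapply(node_px[, 2], clab, mean)
    deg <- integer(n_nodes)
    for (e in edges) {
      deg[e$from] <- deg[e$from] + 1L
      deg[e$to] <- deg[e$to] + 1L
    }
    nodes <- data.frame(id = seq_len(n_nodes),
                        row = as.numeric(rows[as.character(seq_len(n_nodes))]),
                        col = as.numeric(cols[as.character(seq_len(n_nodes))]),
                        degree = deg)
    if (length(contracted)) nodes <- nodes[-contracted, , drop = FALSE]
  } else {
    nodes <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                        degree = integer(0))
  }
  list(nodes = nodes, edges = edges)
}

.arc_length <- function(pix) {
  if (nrow(pix) < 2L) return(0)
  sum(sqrt(diff(pix[, 1])^2 + diff(pix[, 2])^2))
}

#' Build a vessel graph from a label mask
#'
#' Skeletonizes one vessel class and converts the skeleton into a graph of
#' junction/endpoint nodes and centerline edges. Terminal spurs shorter
#' than `min_spur_px` (thinning artifacts) are pruned and the graph
#' re-traced until stable.
#'
#' @param mask integer label matrix (0 background, 1 artery, 2 vein).
#' @param vessel_class `"artery"` or `"vein"` (or the numeric label).
#' @param min_spur_px prune terminal edges shorter than this (px).
#' @return object of class `vessel_graph`: `nodes` (data frame id/row/col/
#'   degree), `edges` (list of `from`, `to`, `pixels` centerline chains),
#'   `skeleton`, `vessel_class`, `flags`.
#' @export
skeletonize_and_build <- function(mask, vessel_class, min_spur_px = 5) {
  code <- .class_code(vessel_class)
  cls <- if (code == 1L) "artery" else if (code == 2L) "vein" else as.character(code)
  bin <- mask == code
  flags <- character(0)
  if (!any(bin)) {
    return(structure(list(nodes = data.frame(id = integer(0), row = numeric(0),
                                             col = numeric(0), degree = integer(0)),
                          edges = list(), skeleton = bin, vessel_class = cls,
                          flags = "empty_vessel_class"),
                     class = "vessel_graph"))
  }
  sk <- skeletonize(bin)
  for (iter in 1:10) {
    g <- .trace_graph(sk)
    if (length(g$edges) <= 1L) break
    deg_of <- function(id) {
      d <- g$nodes$degree[g$nodes$id == id]
      if (length(d)) d else 0L
    }
    spur <- vapply(g$edges, function(e) {
      d1 <- deg_of(e$from); d2 <- deg_of(e$to)
      len <- .arc_length(e$pixels)
      # terminal spur into a junction, or a tiny rasterization self-loop
      ((d1 == 1L || d2 == 1L) && (d1 >= 3L || d2 >= 3L) && len < min_spur_px) ||
        (e$from == e$to && len < 2 * min_spur_px)
    }, logical(1))
    if (!any(spur)) break
    for (e in g$edges[spur]) {
      px <- e$pixels
      if (e$from == e$to) {
        # self-loop: drop its interior, keep the node pixels
        if (nrow(px) > 2L) sk[px[-c(1L, nrow(px)), , drop = FALSE]] <- FALSE
        next
      }
      # keep the junction-side terminal pixel, delete the rest of the spur
      keep_from <- deg_of(e$from) >= 3L
      drop <- if (keep_from) px[-1, , drop = FALSE] else px[-nrow(px), , drop = FALSE]
      sk[drop] <- FALSE
    }
  }
  g <- .trace_graph(sk)
  structure(list(nodes = g$nodes, edges = g$edges, skeleton = sk,
                 vessel_class = cls, flags = flags),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph (%s): %d nodes (%d junctions), %d edges>\n",
              x$vessel_class, nrow(x$nodes), sum(x$nodes$degree >= 3L),
              length(x$edges)))
  invisible(x)
}

# cached ray offset tables, keyed by (angle_step, max_r)
.ray_cache <- new.env(parent = emptyenv())

.ray_step <- 0.5   # sub-pixel marching step along each ray (px)

.ray_offsets <- function(angle_step, max_r) {
  key <- paste(angle_step, max_r)
  if (!is.null(.ray_cache[[key]])) return(.ray_cache[[key]])
  ang <- seq(0, 180 - angle_step, by = angle_step) * pi / 180
  t <- seq(.ray_step, max_r, by = .ray_step)
  # nearest-pixel trace of each continuous ray
  dr <- floor(outer(sin(ang), t) + 0.5)    # n_ang x n_steps
  dc <- floor(outer(cos(ang), t) + 0.5)
  out <- list(dr = dr, dc = dc, t = t, n_ang = length(ang))
  .ray_cache[[key]] <- out
  out
}

# width at one pixel of a binary mask; bin must be logical.
# An edge is declared at the first of two consecutive background samples:
# a single background cell clipped diagonally by the ray is a rasterization
# notch in the band boundary, not the outside of the vessel.
.measure_width_bin <- function(bin, pixel, angle_step = 1, max_r = 50) {
  off <- .ray_offsets(angle_step, max_r)
  nr <- nrow(bin); nc <- ncol(bin)
  edge_t <- function(dr, dc) {
    rr <- pixel[1] + dr; cc <- pixel[2] + dc
    inb <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    vals <- matrix(FALSE, nrow(dr), ncol(dr))
    vals[inb] <- bin[cbind(rr[inb], cc[inb])]
    bg <- !vals
    ex <- bg[, -ncol(bg), drop = FALSE] & bg[, -1, drop = FALSE]
    fb <- max.col(ex, ties.method = "first")
    fb[rowSums(ex) == 0L] <- NA_integer_
    off$t[fb]
  }
  t1 <- edge_t(off$dr, off$dc)
  t2 <- edge_t(-off$dr, -off$dc)
  ok <- !is.na(t1) & !is.na(t2)
  if (!any(ok)) return(NA_real_)
  min(t1[ok] + t2[ok])
}

#' Measure vessel width at a centerline pixel
#'
#' Cross-sectional width by ray search: from the centerline pixel, rays are
#' marched at every `angle_step` degrees in `[0, 180)` and in the opposite
#' direction until the first background pixel; the width is the minimum
#' over angles of the Euclidean distance between the two opposite edge
#' points (the last vessel pixels, plus one pixel for the center sample).
#'
#' @param mask integer label matrix.
#' @param centerline_pixel integer (row, col); must be a vessel pixel.
#' @param angle_step angular resolution in degrees.
#' @param max_r maximum search radius (px); `NA` if no edge found within it.
#' @return width in pixels, or `NA` if the vessel is unbounded within
#'   `max_r` at every angle.
#' @export
measure_width <- function(mask, centerline_pixel, angle_step = 1, max_r = 50) {
  p <- as.integer(centerline_pixel)
  lab <- mask[p[1], p[2]]
  if (lab == 0L) stop("centerline pixel lies on background")
  .measure_width_bin(mask == lab, p, angle_step, max_r)
}

# moving-average smoothing with fixed endpoints: kills the staircase bias
# of 8-connected chains without shortening the segment
.smooth_chain <- function(pix, half = 2L) {
  n <- nrow(pix)
  if (n <= 2L) return(pix)
  out <- pix
  for (i in 2:(n - 1L)) {
    k <- min(half, i - 1L, n - i)
    idx <- (i - k):(i + k)
    out[i, ] <- c(mean(pix[idx, 1]), mean(pix[idx, 2]))
  }
  out
}

#' Extract measured segments from a vessel graph
#'
#' Samples the cross-sectional width every `stride` centerline pixels along
#' each edge (samples within `junction_clearance` px of a junction node are
#' discarded), and computes each segment's arc length and chord length.
#' Arc length is measured on a lightly smoothed copy of the pixel chain
#' (endpoints fixed) to remove the length bias of discrete 8-connected
#' steps.
#'
#' @param graph a `vessel_graph` built from `mask`.
#' @param mask the label matrix the graph was built from.
#' @param stride centerline sampling stride (px).
#' @param junction_clearance discard samples within this distance of a
#'   junction node (px).
#' @param angle_step,max_r passed to the width search.
#' @return list of `vessel_segment` objects: `id`, `vessel_class`, `from`,
#'   `to`, `centerline`, `sample_pos`, `sample_arc`, `widths`,
#'   `path_length`, `chord_length`, `mean_width`, `median_width`, `rank`.
#' @export
segments_with_widths <- function(graph, mask, stride = 3,
                                 junction_clearance = 2,
                                 angle_step = 1, max_r = 50) {
  code <- .class_code(graph$vessel_class)
  bin <- mask == code
  jn <- graph$nodes[graph$nodes$degree >= 3L, , drop = FALSE]
  segs <- vector("list", length(graph$edges))
  for (i in seq_along(graph$edges)) {
    e <- graph$edges[[i]]
    pix <- e$pixels
    n <- nrow(pix)
    sm <- .smooth_chain(pix)
    arc <- c(0, cumsum(sqrt(diff(sm[, 1])^2 + diff(sm[, 2])^2)))
    idx <- seq(1L, n, by = stride)
    if (nrow(jn)) {
      dmin <- sapply(idx, function(j)
        min(sqrt((jn$row - pix[j, 1])^2 + (jn$col - pix[j, 2])^2)))
      idx <- idx[dmin > junction_clearance]
    }
    w <- vapply(idx, function(j)
      .measure_width_bin(bin, pix[j, ], angle_step, max_r), numeric(1))
    keep <- is.finite(w) & w > 0
    segs[[i]] <- structure(list(
      id = i, vessel_class = graph$vessel_class,
      from = e$from, to = e$to,
      centerline = pix,
      sample_pos = pix[idx[keep], , drop = FALSE],
      sample_arc = arc[idx[keep]],
      widths = w[keep],
      path_length = arc[n],
      chord_length = sqrt(sum((pix[n, ] - pix[1, ])^2)),
      mean_width = if (any(keep)) mean(w[keep]) else NA_real_,
      median_width = if (any(keep)) median(w[keep]) else NA_real_,
      n_breaks = 0L, rank = NA_integer_), class = "vessel_segment")
  }
  segs
}

#' @export
print.vessel_segment <- function(x, ...) {
  cat(sprintf(
    "<vessel_segment %d (%s): L=%.1f px, C=%.1f px, width %.1f px (%d samples)%s>\n",
    x$id, x$vessel_class, x$path_length, x$chord_length,
    if (is.na(x$mean_width)) NA else x$mean_width, length(x$widths),
    if (!is.na(x$rank)) sprintf(", rank %d", x$rank) else ""))
  invisible(x)
}

.norm01 <- function(x) {
  x[!is.finite(x)] <- 0
  m <- max(x)
  if (m > 0) x / m else rep(0, length(x))
}

#' Rank and select the most measurable vessels
#'
#' Composite score over length, intensity contrast against the local
#' background, prominence (mean width), and connectivity (uninterrupted
#' chains score highest); the top `k` segments are returned with ranks.
#'
#' @param segments list of `vessel_segment`s.
#' @param image optional [fundus_image()] used for the intensity term
#'   (green-channel contrast vs the in-field median); without it the
#'   intensity term is zero for all segments.
#' @param k number of vessels to keep (default 6).
#' @param weights numeric length-4: length, intensity, prominence,
#'   connectivity weights.
#' @return the selected segments, score-descending, with `$rank` set;
#'   attribute `low_vessel_count` is TRUE when fewer than `k` existed.
#' @export
rank_top_vessels <- function(segments, image = NULL, k = 6,
                             weights = c(0.4, 0.2, 0.3, 0.1)) {
  if (length(segments) == 0L) stop("no segments to rank")
  len <- vapply(segments, `[[`, numeric(1), "path_length")
  prom <- vapply(segments, function(s)
    if (is.na(s$mean_width)) 0 else s$mean_width, numeric(1))
  conn <- vapply(segments, function(s) 1 / (1 + s$n_breaks), numeric(1))
  if (!is.null(image)) {
    g <- unclass(image)[, , 2]
    bg <- median(g[g > 0])
    contrast <- vapply(segments, function(s)
      max(0, bg - mean(g[s$centerline])), numeric(1))
  } else contrast <- rep(0, length(segments))
  score <- weights[1] * .norm01(len) + weights[2] * .norm01(contrast) +
    weights[3] * .norm01(prom) + weights[4] * .norm01(conn)
  topleft_r <- vapply(segments, function(s) min(s$centerline[, 1]), numeric(1))
  topleft_c <- vapply(segments, function(s) min(s$centerline[, 2]), numeric(1))
  ord <- order(-score, -len, topleft_r, topleft_c)
  sel <- head(ord, k)
  out <- segments[sel]
  for (i in seq_along(out)) out[[i]]$rank <- i
  attr(out, "low_vessel_count") <- length(segments) < k
  out
}

#' Extract measured junctions from a graph
#'
#' At every degree-3 or degree-4 node, each incident segment's local width
#' is the median of its width samples within `window` centerline px of the
#' node (just beyond the near-junction exclusion zone); the widest incident
#' segment is the parent (`r0`), the rest are daughters in descending
#' order. Higher-degree nodes are skipped and flagged.
#'
#' @param graph a `vessel_graph`.
#' @param segments segments from [segments_with_widths()] for that graph.
#' @param window arc-length window from the node end (px, default 12:
#'   the 2 px clearance plus 10 px of usable profile).
#' @param parent_rule `"widest"` (default: the widest incident segment is
#'   the parent) or `"od_proximal"` (the incident segment whose far end
#'   lies closest to the optic disc; requires `od_geom`).
#' @param od_geom an `od_geometry`, needed for `parent_rule =
#'   "od_proximal"`.
#' @return list of `junction` objects (`position`, `r0`, `daughters`,
#'   `node_id`); attribute `skipped` counts nodes outside the analyzed
#'   arity.
#' @export
extract_junctions <- function(graph, segments, window = 12,
                              parent_rule = c("widest", "od_proximal"),
                              od_geom = NULL) {
  parent_rule <- match.arg(parent_rule)
  if (parent_rule == "od_proximal" && is.null(od_geom))
    stop("parent_rule 'od_proximal' needs od_geom")
  jnodes <- graph$nodes[graph$nodes$degree %in% c(3L, 4L), , drop = FALSE]
  skipped <- sum(graph$nodes$degree >= 5L)
  out <- list()
  for (i in seq_len(nrow(jnodes))) {
    nid <- jnodes$id[i]
    ws <- numeric(0); far_d <- numeric(0)
    for (s in segments) {
      if (s$from != nid && s$to != nid) next
      if (length(s$widths) == 0L) next
      arc <- s$sample_arc
      d_from_node <- if (s$from == nid) arc else s$path_length - arc
      sel <- d_from_node <= window
      w <- if (any(sel)) median(s$widths[sel]) else s$widths[which.min(d_from_node)]
      ws <- c(ws, w)
      if (parent_rule == "od_proximal") {
        other <- if (s$from == nid) s$to else s$from
        nd <- graph$nodes[graph$nodes$id == other, ]
        far_d <- c(far_d, sqrt((nd$row - od_geom$center[1])^2 +
                                 (nd$col - od_geom$center[2])^2))
      }
    }
    if (length(ws) < 3L) next
    pi_ <- if (parent_rule == "widest") which.max(ws) else which.min(far_d)
    out[[length(out) + 1L]] <- structure(
      list(position = c(jnodes$row[i], jnodes$col[i]),
           r0 = ws[pi_], daughters = sort(ws[-pi_], decreasing = TRUE),
           node_id = nid),
      class = "junction")
  }
  attr(out, "skipped") <- skipped
  out
}

#' @export
print.junction <- function(x, ...) {
  cat(sprintf("<junction at (%.1f, %.1f): r0=%.1f, daughters %s px>\n",
              x$position[1], x$position[2], x$r0,
              paste(sprintf("%.1f", x$daughters), collapse = ", ")))
  invisible(x)
}

#' Export a segment table
#'
#' @param segments list of `vessel_segment`s.
#' @return data frame, one row per segment (id, class, lengths, widths,
#'   rank).
#' @export
segments_as_dataframe <- function(segments) {
  do.call(rbind, lapply(segments, function(s) data.frame(
    id = s$id, vessel_class = s$vessel_class,
    path_length = s$path_length, chord_length = s$chord_length,
    mean_width = s$mean_width, median_width = s$median_width,
    n_samples = length(s$widths), rank = s$rank)))
}
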