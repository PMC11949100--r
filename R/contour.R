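# Contour extraction from label masks.
#
# The cornea class of a segmented anterior-segment image has an
# *incomplete* contour wherever the pterygium occludes the limbus: the
# traced boundary then contains both true limbal-arc points and
# leading-edge points, and the latter behave as outliers for circle
# fitting.  Extraction is deterministic: the largest 8-connected
# component is traced clockwise from its topmost-then-leftmost pixel
# (Moore neighbour tracing).

#' Extract the outer contour of a class region
#'
#' Finds the largest 8-connected component of `class_code` in the mask
#' and returns its outer boundary as an ordered point set: a clockwise
#' Moore-neighbour trace starting from the topmost, then leftmost,
#' boundary pixel, with each boundary pixel reported once (in order of
#' first visit).
#'
#' @param mask Label matrix.
#' @param class Class name or integer code.
#' @return A `contour_points` object: list with `points` (n x 2 matrix of
#'   0-based `(x, y)` pixel coordinates), `class_code`, and
#'   `component_size` (pixel count of the traced component).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(128, 128, boundary_jitter_sd_px = 0))
#' ct <- extract_class_contour(ph$mask, "cornea")
#' nrow(ct$points)
extract_class_contour <- function(mask, class) {
  mask <- validate_mask(mask)
  code <- class_code(class)
  binary <- mask == code
  if (!any(binary)) {
    nm <- names(ptery_classes())[match(code, ptery_classes())]
    stop("empty class: no pixels of class '", nm, "' (code ", code,
         ") in mask", call. = FALSE)
  }
  comp <- largest_component8(binary)
  pts <- moore_trace(comp)
  structure(list(points = pts, class_code = code,
                 component_size = sum(comp)),
            class = "contour_points")
}

# largest 8-connected component of a logical matrix.  EBImage::bwlabel
# labels 4-connected components; labels that touch diagonally are merged
# with a small union-find to obtain 8-connectivity.
largest_component8 <- function(binary) {
  lab <- EBImage::bwlabel(binary)
  lab <- matrix(as.integer(round(lab)), nrow(binary), ncol(binary))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab == 1L)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  H <- nrow(lab); W <- ncol(lab)
  pair_up <- function(a, b) {
    keep <- a > 0L & b > 0L & a != b
    unique(cbind(a[keep], b[keep]))
  }
  # diagonal neighbours: (r, c) with (r+1, c+1) and (r+1, c-1)
  prs <- rbind(
    pair_up(lab[-H, -W], lab[-1, -1]),
    pair_up(lab[-H, -1], lab[-1, -W]))
  if (nrow(prs)) for (i in seq_len(nrow(prs))) union2(prs[i, 1], prs[i, 2])
  roots <- vapply(seq_len(nlab), find, integer(1))
  rlab <- ifelse(lab > 0L, roots[pmax(lab, 1L)], 0L)
  sizes <- tabulate(rlab[rlab > 0L], nbins = nlab)
  best <- which.max(sizes)
  matrix(rlab == best, H, W)
}

# clockwise Moore-neighbour boundary trace of a single component.
# Returns unique boundary pixels as 0-based (x, y) in visit order.
moore_trace <- function(comp) {
  H <- nrow(comp); W <- ncol(comp)
  idx <- which(comp)
  r0 <- ((idx - 1L) %% H) + 1L
  c0 <- ((idx - 1L) %/% H) + 1L
  top <- min(r0)
  left <- min(c0[r0 == top])
  start <- c(top, left)
  # clockwise neighbour offsets in screen coordinates (y down), from East
  off <- rbind(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L),
               c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L))
  fg <- function(r, c) r >= 1L && r <= H && c >= 1L && c <= W && comp[r, c]
  # backtrack starts at the West neighbour (background: start pixel is
  # leftmost in the topmost row)
  path_r <- integer(0); path_c <- integer(0)
  push <- function(p) { path_r[[length(path_r) + 1L]] <<- p[1]
                        path_c[[length(path_c) + 1L]] <<- p[2] }
  push(start)
  cur <- start
  back_dir <- 5L                       # index of West in `off`
  second <- NULL
  max_steps <- 4L * length(idx) + 8L
  for (step in seq_len(max_steps)) {
    found <- FALSE
    d <- back_dir
    for (k in seq_len(8L)) {
      d <- (d %% 8L) + 1L              # next clockwise direction
      nr <- cur[1] + off[d, 1]; nc <- cur[2] + off[d, 2]
      if (fg(nr, nc)) { found <- TRUE; break }
    }
    if (!found) break                  # isolated pixel
    nxt <- c(nr, nc)
    if (is.null(second)) {
      second <- nxt
    } else if (cur[1] == start[1] && cur[2] == start[2] &&
               nxt[1] == second[1] && nxt[2] == second[2]) {
      break                            # closed the loop
    }
    push(nxt)
    # new backtrack direction: points from `nxt` towards the last
    # background pixel checked (the one preceding direction d)
    pd <- ((d - 2L) %% 8L) + 1L
    pr <- cur[1] + off[pd, 1]; pc <- cur[2] + off[pd, 2]
    back_dir <- dir_index(nxt, c(pr, pc), off)
    cur <- nxt
  }
  pts <- cbind(x = path_c - 1L, y = path_r - 1L)
  pts[!duplicated(pts), , drop = FALSE]
}

dir_index <- function(from, to, off) {
  d <- c(to[1] - from[1], to[2] - from[2])
  which(off[, 1] == d[1] & off[, 2] == d[2])[1]
}
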