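# Connected-component labelling with selectable 4/8 connectivity, plus
# Moore-neighbour boundary tracing. Labels are assigned in raster-scan
# order of each component's first pixel (column-major here would differ
# from the usual convention, so scanning is row-major on purpose), which
# gives the deterministic tie-break used by region selection.

assertMask <- function(mask) {
  if (!is.matrix(mask) || length(mask) == 0)
    stop("mask must be a non-empty matrix")
  if (!all(mask %in% c(0L, 1L)))
    stop("mask values must be 0 or 1")
  invisible(TRUE)
}

neighborOffsets <- function(connectivity) {
  if (connectivity == 4)
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  else
    cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
          dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
}

#' Label connected foreground components
#'
#' Breadth-first labelling of foreground (value 1) pixels. Component ids
#' are 1, 2, ... in row-major raster order of each component's first pixel.
#'
#' @param mask 0/1 integer matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of the same shape; 0 marks background.
#' @export
labelComponents <- function(mask, connectivity = 8) {
  assertMask(mask)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  off <- neighborOffsets(connectivity)
  # row-major scan order over column-major linear indices
  scan <- as.vector(t(matrix(seq_len(h * w), h, w)))
  nextLab <- 0L
  for (idx in scan) {
    if (mask[idx] != 1L || lab[idx] != 0L) next
    nextLab <- nextLab + 1L
    frontier <- idx
    lab[idx] <- nextLab
    while (length(frontier)) {
      r <- ((frontier - 1L) %% h) + 1L
      cc <- ((frontier - 1L) %/% h) + 1L
      nr <- rep(r, each = nrow(off)) + rep(off[, 1L], times = length(frontier))
      nc <- rep(cc, each = nrow(off)) + rep(off[, 2L], times = length(frontier))
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      ni <- (nc[ok] - 1L) * h + nr[ok]
      ni <- unique(ni[mask[ni] == 1L & lab[ni] == 0L])
      lab[ni] <- nextLab
      frontier <- ni
    }
  }
  lab
}

# sizes of labelled components, named by label
componentSizes <- function(lab) {
  pos <- lab[lab > 0L]
  if (!length(pos)) return(integer(0))
  tabulate(pos)
}

#' Trace region boundaries
#'
#' Labels the mask's components and returns, per component, the ordered
#' outer-boundary pixel sequence from clockwise Moore-neighbour tracing,
#' starting at the component's first pixel in row-major raster order.
#'
#' @param mask 0/1 integer matrix.
#' @param connectivity 4 or 8, for the component labelling.
#' @return list with `labels` (integer matrix) and `boundaries` (list of
#'   two-column `row`/`col` matrices, one closed traversal per component).
#' @export
traceBoundaries <- function(mask, connectivity = 8) {
  assertMask(mask)
  lab <- labelComponents(mask, connectivity)
  nlab <- max(lab)
  # clockwise Moore neighbourhood starting from W
  moore <- cbind(dr = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
                 dc = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L))
  h <- nrow(mask); w <- ncol(mask)
  inside <- function(r, c) r >= 1L && r <= h && c >= 1L && c <= w
  boundaries <- vector("list", nlab)
  for (lb in seq_len(nlab)) {
    # first pixel in row-major order
    hits <- which(lab == lb)
    rr <- ((hits - 1L) %% h) + 1L
    cc <- ((hits - 1L) %/% h) + 1L
    first <- order(rr, cc)[1L]
    r0 <- rr[first]; c0 <- cc[first]
    if (length(hits) == 1L) {
      boundaries[[lb]] <- cbind(row = r0, col = c0)
      next
    }
    path <- list(c(r0, c0))
    # enter from the W neighbour (backtrack direction index 1)
    r <- r0; c <- c0; backtrack <- 1L
    repeat {
      found <- FALSE
      for (s in seq_len(8L)) {
        d <- ((backtrack - 1L + s - 1L) %% 8L) + 1L
        nr <- r + moore[d, 1L]; nc <- c + moore[d, 2L]
        if (inside(nr, nc) && lab[nr, nc] == lb) {
          # next scan starts one step clockwise past the direction that
          # points back at the pixel we just left (radial sweep)
          backtrack <- ((d + 4L) %% 8L) + 1L
          r <- nr; c <- nc
          found <- TRUE
          break
        }
      }
      if (!found) break                       # isolated pixel (handled above)
      if (r == r0 && c == c0) break           # loop closed
      path[[length(path) + 1L]] <- c(r, c)
      if (length(path) > 4L * length(hits) + 8L) break   # safety stop
    }
    m <- do.call(rbind, path)
    colnames(m) <- c("row", "col")
    boundaries[[lb]] <- m
  }
  list(labels = lab, boundaries = boundaries)
}
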