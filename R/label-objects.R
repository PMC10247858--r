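#' Connected-component labelling of a binary mask
#'
#' Labels connected foreground components under 4- or 8-connectivity.
#' 8-connectivity is the default for mitochondrial masks so thin diagonal
#' tubes stay single objects. Labels are contiguous 1..n and deterministic:
#' components are numbered by their first pixel in column-major raster
#' order. An empty mask yields zero objects.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @param minSize drop objects smaller than this many pixels (default 1,
#'   i.e. keep everything).
#' @return integer matrix; 0 = background, labels 1..n.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[1:2, 1:2] <- TRUE; m[4:5, 4:5] <- TRUE
#' max(labelObjects(m))  # 2
#' @export
labelObjects <- function(mask, connectivity = 8L, minSize = 1L) {
  stopifnot(is.matrix(mask), is.logical(mask), connectivity %in% c(4L, 8L))
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0L, H, W)
  fg <- which(mask)
  if (!length(fg)) return(out)

  vid <- integer(H * W)
  vid[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% H) + 1L
  co <- ((fg - 1L) %/% H) + 1L

  shifts <- list(c(1L, 0L), c(0L, 1L))              # down, right
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))  # both diagonals
  edges <- lapply(shifts, function(s) {
    nr <- r + s[1]; nc <- co + s[2]
    ok <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
    nIdx <- (nc[ok] - 1L) * H + nr[ok]
    hit <- vid[nIdx] > 0L
    cbind(vid[fg[ok]][hit], vid[nIdx][hit])
  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership

  # renumber by first occurrence in raster order, then apply size filter
  first <- !duplicated(memb)
  relabel <- integer(max(memb))
  relabel[memb[first]] <- seq_len(sum(first))
  lab <- relabel[memb]
  if (minSize > 1L) {
    sizes <- tabulate(lab)
    keep <- which(sizes >= minSize)
    remap <- integer(length(sizes))
    remap[keep] <- seq_along(keep)
    lab <- remap[lab]
  }
  out[fg] <- lab
  out
}

#' Pixel coordinates of one labelled object
#'
#' @param labeled integer label matrix.
#' @param label object id.
#' @return integer matrix with columns \code{row}, \code{col}.
#' @export
objectPixels <- function(labeled, label) {
  idx <- which(labeled == label)
  if (!length(idx)) stop("no pixels with label ", label)
  out <- arrayInd(idx, dim(labeled))
  colnames(out) <- c("row", "col")
  out
}
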