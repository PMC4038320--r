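#' Label connected components of a binary map
#'
#' Flood-fill labelling of the foreground (TRUE) pixels of a binary image,
#' with 8- or 4-connectivity.  Labels are assigned in column-major scan
#' order, so label 1 is the component containing the first foreground pixel
#' encountered.
#'
#' @param binary logical (or 0/1 numeric) matrix.
#' @param connectivity 8 (default) or 4.
#' @return list with \code{labels} (integer matrix, 0 = background) and
#'   \code{sizes} (integer vector of component areas, indexed by label).
#' @seealso [detectTarget()]
#' @export
labelComponents <- function(binary, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  b <- binary != 0
  h <- nrow(b); w <- ncol(b)
  labels <- matrix(0L, h, w)
  fg <- which(b)
  if (!length(fg)) return(list(labels = labels, sizes = integer(0L)))

  offR <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)[seq_len(connectivity)]
  offC <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)[seq_len(connectivity)]

  lab <- 0L
  sizes <- integer(0L)
  for (start in fg) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    labels[start] <- lab
    count <- 1L
    frontier <- start
    while (length(frontier)) {
      r <- (frontier - 1L) %% h + 1L
      cc <- (frontier - 1L) %/% h + 1L
      rr <- rep(r, times = length(offR)) + rep(offR, each = length(r))
      ccx <- rep(cc, times = length(offC)) + rep(offC, each = length(cc))
      ok <- rr >= 1L & rr <= h & ccx >= 1L & ccx <= w
      nb <- unique((ccx[ok] - 1L) * h + rr[ok])
      nb <- nb[b[nb] & labels[nb] == 0L]
      labels[nb] <- lab
      count <- count + length(nb)
      frontier <- nb
    }
    sizes[lab] <- count
  }
  list(labels = labels, sizes = sizes)
}
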