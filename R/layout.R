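#' Genome layout
#'
#' A genome layout holds the chromosome table (identifier, physical length in
#' bp, centromere position) together with the ordered marker positions used to
#' genotype tetrads. All positions are 1-based inclusive; BED exports are
#' 0-based half-open.
#'
#' @param chrom character vector of chromosome identifiers.
#' @param length integer vector of chromosome lengths (bp), all > 0.
#' @param centromere integer vector of centromere positions, within
#'   `[1, length]`.
#' @param markers named list (one element per chromosome) of strictly
#'   increasing integer marker positions within `[1, length]`.
#' @return An object of class `genome_layout`: a list with elements `chrom`
#'   (data.frame with columns chrom, length, centromere) and `markers`.
#' @examples
#' gl <- genome_layout("chr1", 1e6, 5e5, list(chr1 = c(100L, 2000L, 9000L)))
#' genome_size(gl)
#' @export
genome_layout <- function(chrom, length, centromere, markers = NULL) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  centromere <- as.numeric(centromere)
  if (anyDuplicated(chrom)) stop("duplicated chromosome ids")
  if (any(length <= 0)) stop("chromosome lengths must be > 0")
  if (any(centromere < 1 | centromere > length)) {
    stop("centromere positions must lie within [1, length]")
  }
  if (is.null(markers)) {
    markers <- stats::setNames(rep(list(integer(0)), length(chrom)), chrom)
  }
  if (!all(chrom %in% names(markers))) {
    stop("markers must be a named list covering every chromosome")
  }
  markers <- markers[chrom]
  for (i in seq_along(chrom)) {
    m <- markers[[i]]
    if (base::length(m) == 0L) next
    if (is.unsorted(m, strictly = TRUE)) {
      stop("marker positions on ", chrom[i], " must be strictly increasing")
    }
    if (m[1] < 1 || m[base::length(m)] > length[i]) {
      stop("marker positions on ", chrom[i], " must lie within [1, length]")
    }
  }
  structure(
    list(
      chrom = data.frame(chrom = chrom, length = length,
                         centromere = centromere, stringsAsFactors = FALSE),
      markers = markers
    ),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  nm <- vapply(x$markers, length, integer(1))
  cat("<genome_layout> ", nrow(x$chrom), " chromosomes, ",
      format(genome_size(x), big.mark = ","), " bp, ",
      sum(nm), " markers\n", sep = "")
  print(cbind(x$chrom, n_markers = nm), row.names = FALSE)
  invisible(x)
}

#' Total genome size of a layout
#'
#' @param layout a [genome_layout()].
#' @return Total length in bp.
#' @export
genome_size <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  sum(layout$chrom$length)
}

#' Kluyveromyces lactis-like genome layout
#'
#' Convenience constructor for the six-chromosome, ~10.7 Mb genome used as the
#' simulator's default study system, with randomly drawn marker maps matching
#' a target marker density and a right-skewed inter-marker spacing
#' distribution (gamma-distributed gaps, shape < 1, so the median gap is well
#' below the mean as in real SNP maps).
#'
#' @param lengths chromosome lengths in bp. Default: six chromosomes totalling
#'   ~10.71 Mb.
#' @param marker_density expected markers per bp (default 0.00279, i.e. ~29.8k
#'   markers over 10.7 Mb; median gap ~187 bp with the default shape).
#' @param spacing_shape gamma shape of inter-marker gaps (default 0.57).
#' @param centromere_frac fractional centromere position per chromosome.
#' @return A [genome_layout()].
#' @export
kl_layout <- function(lengths = c(1060000, 1320000, 1750000, 1750000,
                                  2230000, 2600000),
                      marker_density = 0.00279,
                      spacing_shape = 0.57,
                      centromere_frac = 0.5) {
  k <- length(lengths)
  chrom <- paste0("chr", seq_len(k))
  cen <- pmax(1, round(lengths * centromere_frac))
  markers <- vector("list", k)
  names(markers) <- chrom
  mean_gap <- 1 / marker_density
  for (i in seq_len(k)) {
    n_exp <- ceiling(lengths[i] * marker_density * 1.2) + 10
    gaps <- stats::rgamma(n_exp, shape = spacing_shape,
                          scale = mean_gap / spacing_shape)
    pos <- cumsum(pmax(1, round(gaps)))
    pos <- pos[pos <= lengths[i] - 1]
    while (length(pos) == 0 ||
           pos[length(pos)] < lengths[i] * 0.95) {
      extra <- cumsum(pmax(1, round(stats::rgamma(
        n_exp, shape = spacing_shape, scale = mean_gap / spacing_shape))))
      pos <- c(pos, (if (length(pos)) pos[length(pos)] else 0L) + extra)
      pos <- pos[pos <= lengths[i] - 1]
    }
    markers[[i]] <- as.integer(unique(pos))
  }
  genome_layout(chrom, lengths, cen, markers)
}

#' Read / write a genome layout table
#'
#' The layout TSV has a header and columns `chrom`, `length`, `centromere`.
#' Marker positions travel with segregation files, so `read_layout()` returns
#' a layout with empty marker lists unless `markers` is supplied.
#'
#' @param path file path.
#' @param markers optional named list of marker positions.
#' @return `read_layout()` returns a [genome_layout()]; `write_layout()`
#'   returns `path` invisibly.
#' @export
read_layout <- function(path, markers = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "length", "centromere")
  if (!all(need %in% names(d))) {
    stop("layout file must have columns: ", paste(need, collapse = ", "))
  }
  genome_layout(d$chrom, d$length, d$centromere, markers)
}

#' @rdname read_layout
#' @param layout a [genome_layout()].
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  utils::write.table(layout$chrom, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
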