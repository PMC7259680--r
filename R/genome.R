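#' Define the simulated genome
#'
#' The simulated genome is a set of chromosomes with a uniform recombination
#' map. The default mirrors the standard layout used throughout the package:
#' five chromosomes of 10 Mb each with a recombination rate of 4 cM/Mb.
#' Coordinates are 0-based and half-open; positions may also be addressed by a
#' single global coordinate obtained by concatenating chromosomes.
#'
#' @param chromosome_mb Numeric vector of chromosome lengths in Mb.
#' @param recombination_cm_mb Recombination rate(s) in cM/Mb, recycled across
#'   chromosomes.
#'
#' @return An object of class `genome_layout` with elements
#'   `chrom_len` (bp), `chrom_start` (global 0-based starts),
#'   `recombination_cm_mb`, `cross_mean` (expected crossovers per chromosome
#'   per meiosis) and `genome_size` (bp).
#' @examples
#' g <- genome_layout()
#' g$genome_size # 50 Mb
#' @export
genome_layout <- function(chromosome_mb = rep(10, 5), recombination_cm_mb = 4) {
  if (length(chromosome_mb) < 1 || any(!is.finite(chromosome_mb)) ||
      any(chromosome_mb <= 0)) {
    stop("chromosome lengths must be positive and finite", call. = FALSE)
  }
  rr <- rep_len(recombination_cm_mb, length(chromosome_mb))
  if (any(!is.finite(rr)) || any(rr < 0)) {
    stop("recombination rates must be non-negative", call. = FALSE)
  }
  chrom_len <- as.integer(round(chromosome_mb * 1e6))
  genome_size <- sum(as.numeric(chrom_len))
  if (genome_size >= 2^31) {
    stop("total genome size must be below 2^31 bp", call. = FALSE)
  }
  structure(
    list(
      chrom_len = chrom_len,
      chrom_start = as.integer(cumsum(c(0, as.numeric(chrom_len)))[seq_along(chrom_len)]),
      recombination_cm_mb = rr,
      # a rate of r cM/Mb over L Mb gives r*L/100 expected crossovers
      cross_mean = rr * (chrom_len / 1e6) / 100,
      genome_size = genome_size
    ),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", length(x$chrom_len), " chromosomes, ",
      format(x$genome_size / 1e6), " Mb total; recombination ",
      paste(unique(x$recombination_cm_mb), collapse = "/"), " cM/Mb\n", sep = "")
  invisible(x)
}

#' Place piRNA clusters on a genome
#'
#' One dual-strand piRNA cluster is placed at the left end of every
#' chromosome. The requested total cluster size, expressed as a percent of
#' the genome, is divided equally among chromosomes and rounded to the
#' nearest base pair per chromosome (so very small percentages on small toy
#' genomes can legitimately round to zero). The percent actually realized
#' after rounding is recorded in the returned object.
#'
#' @param layout A [genome_layout()].
#' @param cluster_percent Total cluster size as a percent of the genome,
#'   in `[0, 100]`.
#'
#' @return An object of class `cluster_map` with per-chromosome cluster
#'   lengths (`cluster_len`, bp), the requested and realized percent, and the
#'   originating layout.
#' @examples
#' cm <- build_cluster_map(genome_layout(), 1)
#' cm$cluster_len # 100 kb on each of the five chromosomes
#' @export
build_cluster_map <- function(layout, cluster_percent) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.numeric(cluster_percent) || length(cluster_percent) != 1 ||
      !is.finite(cluster_percent) || cluster_percent < 0 || cluster_percent > 100) {
    stop("cluster_percent must be a single value in [0, 100]", call. = FALSE)
  }
  k <- length(layout$chrom_len)
  per_chrom <- round(cluster_percent / 100 * layout$genome_size / k)
  cluster_len <- as.integer(pmin(per_chrom, layout$chrom_len))
  structure(
    list(
      layout = layout,
      cluster_len = cluster_len,
      cluster_percent = cluster_percent,
      realized_percent = 100 * sum(as.numeric(cluster_len)) / layout$genome_size
    ),
    class = "cluster_map"
  )
}

#' @export
print.cluster_map <- function(x, ...) {
  cat("<cluster_map> ", format(x$realized_percent), "% of genome (",
      paste(x$cluster_len, collapse = ", "), " bp at chromosome starts)\n",
      sep = "")
  invisible(x)
}

#' Test whether positions fall inside a piRNA cluster
#'
#' Clusters occupy the half-open interval `[0, cluster_len)` at the start of
#' each chromosome.
#'
#' @param map A [build_cluster_map()] result.
#' @param chromosome 1-based chromosome index (vectorized).
#' @param offset 0-based bp offset within the chromosome (vectorized).
#' @return Logical vector.
#' @examples
#' cm <- build_cluster_map(genome_layout(), 1)
#' is_in_cluster(cm, 1, c(0, 99999, 100000)) # TRUE TRUE FALSE
#' @export
is_in_cluster <- function(map, chromosome, offset) {
  stopifnot(inherits(map, "cluster_map"))
  n <- max(length(chromosome), length(offset))
  chromosome <- rep_len(as.integer(chromosome), n)
  offset <- rep_len(as.numeric(offset), n)
  if (any(is.na(chromosome)) || any(chromosome < 1) ||
      any(chromosome > length(map$layout$chrom_len))) {
    stop("chromosome index out of bounds", call. = FALSE)
  }
  if (any(is.na(offset)) || any(offset < 0) ||
      any(offset >= map$layout$chrom_len[chromosome])) {
    stop("offset out of bounds for its chromosome", call. = FALSE)
  }
  offset < map$cluster_len[chromosome]
}

#' Cluster size as a percent of the genome
#'
#' Helper for the back-of-envelope arithmetic used to place real species on
#' the simulated cluster-size axis: e.g. summed pachytene piRNA clusters of
#' 3.16 Mb on a 3,000 Mb genome are ~0.105% of the genome, and a 300 kb
#' flamenco locus on a 200 Mb genome is 0.15%.
#'
#' @param total_cluster_mb Summed cluster length, Mb.
#' @param genome_mb Genome size, Mb.
#' @return Percent of the genome occupied by clusters.
#' @examples
#' cluster_percent_of_genome(3.16, 3000) # ~0.105
#' cluster_percent_of_genome(0.3, 200)   # 0.15
#' @export
cluster_percent_of_genome <- function(total_cluster_mb, genome_mb) {
  if (any(!is.finite(genome_mb)) || any(genome_mb <= 0)) {
    stop("genome size must be positive", call. = FALSE)
  }
  if (any(!is.finite(total_cluster_mb)) || any(total_cluster_mb < 0)) {
    stop("cluster length must be non-negative", call. = FALSE)
  }
  100 * total_cluster_mb / genome_mb
}

# global 0-based coordinate <-> (chromosome, offset) helpers ------------------

#' Convert between local and global genome coordinates
#'
#' Haplotypes store insertion positions as single 0-based global coordinates
#' over the concatenated chromosomes; these helpers translate to and from
#' (chromosome, offset) pairs.
#'
#' @param layout A [genome_layout()].
#' @param chromosome 1-based chromosome index.
#' @param offset 0-based offset within the chromosome.
#' @param position 0-based global coordinate.
#' @return `global_position()` returns global coordinates;
#'   `local_position()` returns a data.frame with `chromosome` and `offset`.
#' @export
global_position <- function(layout, chromosome, offset) {
  stopifnot(inherits(layout, "genome_layout"))
  n <- max(length(chromosome), length(offset))
  chromosome <- rep_len(as.integer(chromosome), n)
  offset <- rep_len(as.numeric(offset), n)
  if (any(chromosome < 1) || any(chromosome > length(layout$chrom_len))) {
    stop("chromosome index out of bounds", call. = FALSE)
  }
  if (any(offset < 0) || any(offset >= layout$chrom_len[chromosome])) {
    stop("offset out of bounds for its chromosome", call. = FALSE)
  }
  as.integer(layout$chrom_start[chromosome] + offset)
}

#' @rdname global_position
#' @export
local_position <- function(layout, position) {
  stopifnot(inherits(layout, "genome_layout"))
  position <- as.numeric(position)
  if (any(position < 0) || any(position >= layout$genome_size)) {
    stop("global position out of bounds", call. = FALSE)
  }
  chrom <- findInterval(position, layout$chrom_start)
  data.frame(chromosome = chrom,
             offset = as.integer(position - layout$chrom_start[chrom]))
}
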