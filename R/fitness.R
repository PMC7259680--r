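#' Fitness models for TE-carrying hosts
#'
#' Host fitness declines with the number of deleterious TE insertions. Four
#' functional forms are supported, matching the standard population-genetics
#' treatments of TE load:
#'
#' * `"linear"`: `w = 1 - x * n`, with `n` the diploid copy number;
#' * `"dominance"`: `w = 1 - 2*x*i_hom - 2*h*x*i_het`, with `i_hom`/`i_het`
#'   the homozygous/heterozygous insertion sites (`h = 0` recessive,
#'   `h = 0.5` additive -- identical to linear -- and `h = 1` dominant);
#' * `"epistatic"`: `w = 1 - x * n^t` (`t = 1` linear, `t > 1` steep
#'   synergistic decline, `t < 1` diminishing);
#' * `"site_specific"`: `w = 1 - sum(x_i)` with heterogeneous per-site
#'   effects drawn from discrete classes (e.g. strong/moderate/weak).
#'
#' Fitness is clamped to `[0, 1]`: individuals whose load would push fitness
#' negative simply contribute no offspring. By default TE insertions inside
#' piRNA clusters are cost-free (`x = 0` for cluster insertions) and excluded
#' from the copy number `n`; setting `cluster_insertions_neutral = FALSE`
#' makes cluster insertions as deleterious as any other insertion.
#'
#' Dominance and epistasis cannot be combined: the model is either the
#' dominance form, the epistatic form (which subsumes linear at `t = 1`), or
#' the site-specific form.
#'
#' @param x Selection coefficient per insertion (per-copy fitness cost).
#' @param form One of `"linear"`, `"dominance"`, `"epistatic"`,
#'   `"site_specific"`.
#' @param h Heterozygous (dominance) effect in `[0, 1]`; dominance form only.
#' @param t Epistasis exponent (> 0); epistatic form only.
#' @param site_effects Numeric vector of per-site effect sizes;
#'   site-specific form only.
#' @param site_proportions Proportions of sites in each effect class;
#'   defaults to equal proportions. Must sum to 1.
#' @param cluster_insertions_neutral Are insertions inside piRNA clusters
#'   cost-free (and excluded from `n`)? Default `TRUE`.
#'
#' @return An object of class `fitness_model`.
#' @examples
#' fitness_model(x = 0.01)                      # linear, the baseline
#' fitness_model(x = 0.01, form = "dominance", h = 0)  # fully recessive
#' @export
fitness_model <- function(x = 0.01,
                          form = c("linear", "dominance", "epistatic", "site_specific"),
                          h = 0.5, t = 1,
                          site_effects = NULL, site_proportions = NULL,
                          cluster_insertions_neutral = TRUE) {
  form <- match.arg(form)
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0) {
    stop("x must be a single non-negative number", call. = FALSE)
  }
  if (!is.finite(h) || h < 0 || h > 1) {
    stop("h must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(t) || t <= 0) {
    stop("t must be positive", call. = FALSE)
  }
  if (form == "dominance" && t != 1) {
    stop("dominance and epistasis cannot be combined (set t = 1)", call. = FALSE)
  }
  if (form == "site_specific") {
    if (is.null(site_effects) || length(site_effects) < 1 ||
        any(!is.finite(site_effects)) || any(site_effects < 0)) {
      stop("site_specific form needs non-negative site_effects", call. = FALSE)
    }
    if (is.null(site_proportions)) {
      site_proportions <- rep(1 / length(site_effects), length(site_effects))
    }
    if (length(site_proportions) != length(site_effects) ||
        any(site_proportions < 0) ||
        abs(sum(site_proportions) - 1) > 1e-8) {
      stop("site_proportions must match site_effects and sum to 1", call. = FALSE)
    }
  } else if (!is.null(site_effects)) {
    stop("site_effects are only meaningful with form = 'site_specific'",
         call. = FALSE)
  }
  structure(
    list(x = x, form = form, h = h, t = t,
         site_effects = site_effects,
         site_proportions = site_proportions,
         cluster_insertions_neutral = isTRUE(cluster_insertions_neutral)),
    class = "fitness_model"
  )
}

#' @export
print.fitness_model <- function(x, ...) {
  desc <- switch(x$form,
    linear = sprintf("w = 1 - %g n", x$x),
    dominance = sprintf("w = 1 - 2(%g) i_hom - 2(%g)(%g) i_het", x$x, x$h, x$x),
    epistatic = sprintf("w = 1 - %g n^%g", x$x, x$t),
    site_specific = sprintf("w = 1 - sum(x_i), classes {%s}",
                            paste(x$site_effects, collapse = ", ")))
  cat("<fitness_model> ", desc,
      if (x$cluster_insertions_neutral) " [cluster insertions neutral]"
      else " [cluster insertions deleterious]", "\n", sep = "")
  invisible(x)
}

#' Elementary fitness functions
#'
#' Pure, vectorized forms of the four fitness functions, all clamped to
#' `[0, 1]`. These are the reference implementations used to validate the
#' simulation engine; `dominance_fitness()` with `h = 0.5` and
#' `epistatic_fitness()` with `t = 1` reduce exactly to `linear_fitness()`,
#' and `mixed_effects_fitness()` with constant effects does too.
#'
#' @param n Diploid TE copy number (non-negative).
#' @param x Per-copy selection coefficient.
#' @param i_hom,i_het Numbers of homozygous and heterozygous insertion sites.
#' @param h Heterozygous effect in `[0, 1]`.
#' @param t Epistasis exponent (> 0).
#' @param effects Numeric vector (multiset) of per-copy effect sizes.
#' @return Fitness value(s) in `[0, 1]`.
#' @examples
#' linear_fitness(50, 0.01)              # 0.5
#' dominance_fitness(0, 50, 0.01, h = 0) # 1: recessive, no homozygotes
#' epistatic_fitness(10, 0.01, 1.5)      # 1 - 0.01 * 10^1.5
#' mixed_effects_fitness(c(0.1, 0.001))  # 0.899
#' @export
linear_fitness <- function(n, x) {
  stopifnot(all(n >= 0), all(x >= 0))
  pmin(1, pmax(0, 1 - x * n))
}

#' @rdname linear_fitness
#' @export
dominance_fitness <- function(i_hom, i_het, x, h) {
  stopifnot(all(i_hom >= 0), all(i_het >= 0), all(x >= 0),
            all(h >= 0), all(h <= 1))
  pmin(1, pmax(0, 1 - 2 * x * i_hom - 2 * h * x * i_het))
}

#' @rdname linear_fitness
#' @export
epistatic_fitness <- function(n, x, t) {
  stopifnot(all(n >= 0), all(x >= 0), all(t > 0))
  pmin(1, pmax(0, 1 - x * ifelse(n == 0, 0, n^t)))
}

#' @rdname linear_fitness
#' @export
mixed_effects_fitness <- function(effects) {
  stopifnot(all(effects >= 0))
  min(1, max(0, 1 - sum(effects)))
}

# Per-site effect sizes for the site-specific model. The effect class of a
# SITE is a deterministic hash of its genomic position (equivalent to
# pre-painting the genome with effect classes at the configured proportions),
# so homozygous copies share one effect and effects survive inheritance.
site_effect_of <- function(position, model) {
  u <- cpp_site_unif(as.integer(position))
  idx <- findInterval(u, cumsum(model$site_proportions),
                      left.open = FALSE) + 1L
  idx[idx > length(model$site_effects)] <- length(model$site_effects)
  model$site_effects[idx]
}

#' Evaluate the fitness of a diploid genotype
#'
#' Reference (R-level) evaluation of an individual's fitness under a
#' [fitness_model()], given the two haplotypes as sorted global insertion
#' positions. Insertions inside piRNA clusters are cost-free and excluded
#' from the copy number when the model treats clusters as neutral.
#'
#' This routine is deliberately independent of the C++ engine's fitness code
#' path: the test suite uses it to cross-check the engine's cached fitness.
#'
#' @param individual A list with elements `h1` and `h2`: sorted 0-based
#'   global insertion positions of the two haplotypes.
#' @param map A [build_cluster_map()] result.
#' @param model A [fitness_model()].
#' @return A single fitness value in `[0, 1]`.
#' @examples
#' cm <- build_cluster_map(genome_layout(), 1)
#' ind <- list(h1 = c(0L, 50L), h2 = integer(0)) # two cluster insertions
#' evaluate_fitness(ind, cm, fitness_model(x = 0.01)) # 1: clusters cost-free
#' @export
evaluate_fitness <- function(individual, map, model) {
  stopifnot(inherits(map, "cluster_map"), inherits(model, "fitness_model"))
  h1 <- as.integer(individual$h1)
  h2 <- as.integer(individual$h2)
  layout <- map$layout
  in_clu <- function(p) {
    if (length(p) == 0) return(logical(0))
    chrom <- findInterval(p, layout$chrom_start)
    (p - layout$chrom_start[chrom]) < map$cluster_len[chrom]
  }
  if (model$cluster_insertions_neutral) {
    c1 <- h1[!in_clu(h1)]
    c2 <- h2[!in_clu(h2)]
  } else {
    c1 <- h1
    c2 <- h2
  }
  n <- length(c1) + length(c2)
  switch(model$form,
    linear = linear_fitness(n, model$x),
    epistatic = epistatic_fitness(n, model$x, model$t),
    dominance = {
      i_hom <- length(intersect(c1, c2))
      dominance_fitness(i_hom, n - 2 * i_hom, model$x, model$h)
    },
    site_specific = mixed_effects_fitness(site_effect_of(c(c1, c2), model))
  )
}
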