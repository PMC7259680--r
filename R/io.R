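#' Parse a simulation configuration from command-line style flags
#'
#' Accepts the flag dialect used by classic invasion-simulation tools, so a
#' published command line can be replayed directly:
#'
#' ```
#' --genome Mb:10,10,10,10,10   chromosome sizes in Mb
#' --rr cM_Mb:4,4,4,4,4         recombination rate per chromosome
#' --cluster kb:each:100        one 100 kb cluster per chromosome end
#' --cluster pct:1              ... or total cluster size as percent of genome
#' --basepop seg:1000           seed insertions segregating at 1/2N
#' --u 0.1  --x 0.01  --N 1000  --gen 5000
#' --t 1.5                      epistasis exponent (w = 1 - x n^t)
#' --nsmodel het:0.0            dominance model (recessive)
#' --nsmodel site:0.1,0.001     heterogeneous per-site effects
#' --seed 42
#' ```
#'
#' `--t` (with t != 1) and `--nsmodel` are mutually exclusive: the dominance
#' and site-effect models are alternatives to the epistatic form, and their
#' combination is undefined. `--nsmodel het:0.5` is the additive model and is
#' accepted together with the default `--t 1`.
#'
#' @param args Character vector of flags and values (as from
#'   [base::commandArgs()]), or a length-1 path to a text file containing
#'   the same tokens (whitespace-separated; `#` starts a comment).
#' @return A [simulation_config()].
#' @examples
#' cfg <- parse_config(c("--cluster", "kb:each:100", "--u", "0.1"))
#' cfg$cluster_percent # 1
#' @export
parse_config <- function(args) {
  if (length(args) == 1 && !startsWith(args, "--") && file.exists(args)) {
    lines <- sub("#.*$", "", readLines(args, warn = FALSE))
    args <- unlist(strsplit(trimws(lines), "[[:space:]]+"))
    args <- args[nzchar(args)]
  }
  if (length(args) %% 2 != 0) {
    stop("flags must come in --key value pairs", call. = FALSE)
  }
  keys <- args[c(TRUE, FALSE)]
  vals <- args[c(FALSE, TRUE)]
  if (!all(startsWith(keys, "--"))) {
    stop("expected flags starting with '--', got: ",
         paste(keys[!startsWith(keys, "--")], collapse = ", "), call. = FALSE)
  }
  keys <- sub("^--", "", keys)
  known <- c("genome", "rr", "cluster", "basepop", "u", "x", "N", "gen",
             "t", "nsmodel", "seed", "cluster-deleterious")
  if (any(!keys %in% known)) {
    stop("unknown flag(s): ", paste(keys[!keys %in% known], collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(keys)) {
    stop("duplicated flag(s): ", paste(unique(keys[duplicated(keys)]),
                                       collapse = ", "), call. = FALSE)
  }
  flag <- function(key, default = NULL) {
    if (key %in% keys) vals[match(key, keys)] else default
  }
  num <- function(key, default) {
    v <- flag(key)
    if (is.null(v)) return(default)
    out <- suppressWarnings(as.numeric(v))
    if (is.na(out)) stop("malformed value for --", key, ": ", v, call. = FALSE)
    out
  }
  tagged <- function(key, tag) {
    # "tag:payload" -> payload, or NULL if the flag is absent
    v <- flag(key)
    if (is.null(v)) return(NULL)
    if (!startsWith(v, paste0(tag, ":"))) return(NA_character_)
    sub(paste0("^", tag, ":"), "", v)
  }
  nums <- function(s, key) {
    out <- suppressWarnings(as.numeric(strsplit(s, ",")[[1]]))
    if (length(out) == 0 || any(is.na(out))) {
      stop("malformed value for --", key, call. = FALSE)
    }
    out
  }

  genome_mb <- if (is.null(flag("genome"))) rep(10, 5) else {
    v <- tagged("genome", "Mb")
    if (is.na(v)) stop("--genome expects Mb:<sizes>", call. = FALSE)
    nums(v, "genome")
  }
  rr <- if (is.null(flag("rr"))) 4 else {
    v <- tagged("rr", "cM_Mb")
    if (is.na(v)) stop("--rr expects cM_Mb:<rates>", call. = FALSE)
    nums(v, "rr")
  }
  layout <- genome_layout(genome_mb, rr)

  cluster_percent <- 0
  if (!is.null(flag("cluster"))) {
    v <- flag("cluster")
    if (startsWith(v, "kb:each:")) {
      kb <- nums(sub("^kb:each:", "", v), "cluster")
      if (length(kb) != 1) stop("--cluster kb:each: expects one size", call. = FALSE)
      cluster_percent <- 100 * kb * 1000 * length(layout$chrom_len) /
        layout$genome_size
    } else if (startsWith(v, "pct:")) {
      cluster_percent <- nums(sub("^pct:", "", v), "cluster")
    } else {
      stop("--cluster expects kb:each:<kb> or pct:<percent>", call. = FALSE)
    }
  }

  seed_insertions <- if (is.null(flag("basepop"))) 1000 else {
    v <- tagged("basepop", "seg")
    if (is.na(v)) stop("--basepop expects seg:<count>", call. = FALSE)
    nums(v, "basepop")
  }

  x <- num("x", 0.01)
  t_exp <- num("t", 1)
  neutral <- is.null(flag("cluster-deleterious")) ||
    !identical(flag("cluster-deleterious"), "yes")

  ns <- flag("nsmodel")
  if (!is.null(ns) && t_exp != 1) {
    stop("--t and --nsmodel cannot be combined: the dominance/site models ",
         "are alternatives to the epistatic fitness function", call. = FALSE)
  }
  fitness <- if (is.null(ns)) {
    if (t_exp == 1) {
      fitness_model(x = x, cluster_insertions_neutral = neutral)
    } else {
      fitness_model(x = x, form = "epistatic", t = t_exp,
                    cluster_insertions_neutral = neutral)
    }
  } else if (startsWith(ns, "het:")) {
    h <- nums(sub("^het:", "", ns), "nsmodel")
    fitness_model(x = x, form = "dominance", h = h,
                  cluster_insertions_neutral = neutral)
  } else if (startsWith(ns, "site:")) {
    eff <- nums(sub("^site:", "", ns), "nsmodel")
    fitness_model(x = x, form = "site_specific", site_effects = eff,
                  cluster_insertions_neutral = neutral)
  } else {
    stop("--nsmodel expects het:<h> or site:<effects>", call. = FALSE)
  }

  seed <- flag("seed")
  simulation_config(
    layout = layout,
    cluster_percent = cluster_percent,
    u = num("u", 0.1),
    fitness = fitness,
    N = num("N", 1000),
    seed_insertions = seed_insertions,
    generations = num("gen", 5000),
    rng_seed = if (is.null(seed)) NULL else as.integer(num("seed", NA))
  )
}

# ---- TSV output with a commented metadata header ---------------------------

format_meta <- function(meta) {
  vapply(names(meta), function(k) {
    v <- meta[[k]]
    paste0("# ", k, ": ", paste(format(v, digits = 17), collapse = ","))
  }, "")
}

write_tsv_with_header <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_meta(meta), con)
  df <- as.data.frame(df)
  num_cols <- vapply(df, is.numeric, TRUE)
  df[num_cols] <- lapply(df[num_cols], function(v) format(v, digits = 17,
                                                          trim = TRUE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_with_header <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- trimws(sub("^[^:]*:\\s*", "", kv))
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  df <- if (length(body) > 1) {
    utils::read.delim(text = body, sep = "\t", stringsAsFactors = FALSE)
  } else {
    cols <- strsplit(body, "\t")[[1]]
    as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  }
  out <- tibble::as_tibble(df)
  attr(out, "meta") <- meta
  out
}

#' Write and read result tables
#'
#' Trajectories and sweep tables are written as plain TSV with a commented
#' (`#`) metadata header holding the run's configuration, seed, software
#' version and stop reason -- enough to re-run the simulation
#' bit-identically. Numeric values are printed at full precision so a
#' write/read round trip is lossless.
#'
#' @param invasion An [run_invasion()] result.
#' @param sweep A [run_sweep()] result.
#' @param path Output file path.
#' @return `write_*` return the path invisibly; `read_results()` returns a
#'   tibble with the header in `attr(, "meta")`.
#' @export
write_trajectory <- function(invasion, path) {
  cfg <- invasion$config
  meta <- list(
    type = "trajectory",
    trapsim_version = as.character(utils::packageVersion("trapsim")),
    status = invasion$status,
    stop_reason = invasion$stop_reason,
    min_fitness = invasion$min_fitness,
    min_fitness_generation = invasion$min_fitness_generation,
    generations_run = invasion$generations_run,
    N = cfg$N, u = cfg$u, x = cfg$fitness$x,
    fitness_form = cfg$fitness$form, h = cfg$fitness$h, t = cfg$fitness$t,
    cluster_percent = cfg$cluster_percent,
    seed_insertions = cfg$seed_insertions,
    generations = cfg$generations,
    extinction_threshold = cfg$extinction_threshold,
    copy_cap = cfg$copy_cap,
    rng_seed = if (is.null(cfg$rng_seed)) "NA" else cfg$rng_seed
  )
  write_tsv_with_header(invasion$trajectory, path, meta)
}

#' @rdname write_trajectory
#' @export
write_sweep <- function(sweep, path) {
  spec <- attr(sweep, "spec")
  meta <- list(
    type = "sweep",
    trapsim_version = as.character(utils::packageVersion("trapsim")),
    n_sims = spec$n_sims,
    cluster_percent = spec$cluster_percent, u = spec$u, x = spec$x,
    N = spec$N, h = spec$h, t = spec$t,
    fitness_form = spec$fitness_form,
    seed_insertions = spec$seed_insertions,
    generations = spec$generations,
    master_seed = if (is.null(spec$master_seed)) "NA" else spec$master_seed
  )
  write_tsv_with_header(sweep, path, meta)
}

#' @rdname write_trajectory
#' @export
read_results <- function(path) {
  read_tsv_with_header(path)
}
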