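# Tabular interchange: TSV with '#'-prefixed comment headers; JSON for
# structured results; JSON or YAML for configs.

write_tsv_commented <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

check_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
}

check_range <- function(df, col, lo, hi, path) {
  v <- df[[col]]
  if (!is.numeric(v) || anyNA(v)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1L]
    stop("file ", path, ": column '", col, "', row ", bad,
         " is not a finite number")
  }
  bad <- which(v < lo | v > hi)
  if (length(bad) > 0) {
    stop("file ", path, ": column '", col, "', row ", bad[1L],
         " has value ", v[bad[1L]], " outside [", lo, ", ", hi, "]")
  }
  invisible(TRUE)
}

#' Write and read deterministic drive trajectories
#'
#' Trajectories serialise to TSV with columns `generation` and `p`;
#' parameter provenance travels in `#`-prefixed comment lines.
#'
#' @param traj A `drive_trajectory` (see [drive_trajectory()]).
#' @param path File path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a data frame with validated `generation` and `p` columns.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(is.data.frame(traj), all(c("generation", "p") %in% names(traj)))
  pars <- attr(traj, "params")
  comments <- if (inherits(pars, "drive_params")) {
    sprintf("k=%g w11=%g w12=%g w22=%g F=%g",
            pars$k, pars$w11, pars$w12, pars$w22, pars$F)
  } else character()
  write_tsv_commented(traj[c("generation", "p")], path, comments)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read_tsv_commented(path)
  check_columns(df, c("generation", "p"), path)
  check_range(df, "p", 0, 1, path)
  if (is.unsorted(df$generation, strictly = TRUE)) {
    stop("file ", path, ": 'generation' must be strictly increasing")
  }
  df
}

#' Write and read observed allele-frequency trajectories
#'
#' Experimental-evolution observations use a TSV with columns `replicate`,
#' `generation`, `freq`, `effective_n` — the schema produced by
#' [sim_evolution_trajectories()] and consumed by [fit_linked_cost()].
#'
#' @param data Data frame with the four columns above.
#' @param path File path.
#' @param comments Optional character vector of comment lines.
#' @return `write_trajectories` returns `path` invisibly;
#'   `read_trajectories` the validated data frame.
#' @export
write_trajectories <- function(data, path, comments = character()) {
  stopifnot(is.data.frame(data))
  check_columns(data, c("replicate", "generation", "freq", "effective_n"),
                "<in-memory data>")
  write_tsv_commented(data[c("replicate", "generation", "freq", "effective_n")],
                      path, comments)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- read_tsv_commented(path)
  check_columns(df, c("replicate", "generation", "freq", "effective_n"), path)
  check_range(df, "freq", 0, 1, path)
  check_range(df, "generation", 0, Inf, path)
  check_range(df, "effective_n", 1, Inf, path)
  df
}

#' Write and read zygote genotype count tables
#'
#' Single-observation TSV with columns `hom1`, `het`, `hom2`, `p_initial`.
#'
#' @param counts A [zygote_counts()] object.
#' @param path File path.
#' @return `write_zygote_counts` returns `path` invisibly;
#'   `read_zygote_counts` a [zygote_counts()] object.
#' @export
write_zygote_counts <- function(counts, path) {
  stopifnot(inherits(counts, "zygote_counts"))
  write_tsv_commented(data.frame(hom1 = counts$n_hom1, het = counts$n_het,
                                 hom2 = counts$n_hom2,
                                 p_initial = counts$p_initial),
                      path)
}

#' @rdname write_zygote_counts
#' @export
read_zygote_counts <- function(path) {
  df <- read_tsv_commented(path)
  check_columns(df, c("hom1", "het", "hom2", "p_initial"), path)
  if (nrow(df) != 1L) stop("file ", path, " must contain exactly one row")
  check_range(df, "hom1", 0, Inf, path)
  check_range(df, "het", 0, Inf, path)
  check_range(df, "hom2", 0, Inf, path)
  check_range(df, "p_initial", 0, 1, path)
  zygote_counts(df$hom1, df$het, df$hom2, df$p_initial)
}

#' Write and read cell-census tables
#'
#' Single-observation TSV with columns `V`, `Z`, `A`, `S` (vegetative
#' cells, zygotes, asci, free spores).
#'
#' @param census A `cell_census` (see [sim_census()]) or a list with fields
#'   `V`, `Z`, `A`, `S`.
#' @param path File path.
#' @return `write_census` returns `path` invisibly; `read_census` a
#'   `cell_census` list.
#' @export
write_census <- function(census, path) {
  stopifnot(all(c("V", "Z", "A", "S") %in% names(census)))
  write_tsv_commented(data.frame(V = census$V, Z = census$Z, A = census$A,
                                 S = census$S), path)
}

#' @rdname write_census
#' @export
read_census <- function(path) {
  df <- read_tsv_commented(path)
  check_columns(df, c("V", "Z", "A", "S"), path)
  if (nrow(df) != 1L) stop("file ", path, " must contain exactly one row")
  for (col in c("V", "Z", "A", "S")) check_range(df, col, 0, Inf, path)
  structure(list(V = as.integer(df$V), Z = as.integer(df$Z),
                 A = as.integer(df$A), S = as.integer(df$S)),
            class = "cell_census")
}

#' Write and read progeny marker-genotype tables
#'
#' TSV with one row per progeny and one column per marker (`m1`, `m2`, ...),
#' values 1/2 for parental origin.
#'
#' @param progeny Data frame as produced by [sim_progeny_table()].
#' @param path File path.
#' @return `write_progeny_table` returns `path` invisibly;
#'   `read_progeny_table` the validated data frame with the
#'   `parental_genotypes` attribute reattached.
#' @export
write_progeny_table <- function(progeny, path) {
  stopifnot(is.data.frame(progeny), ncol(progeny) >= 2)
  write_tsv_commented(progeny, path)
}

#' @rdname write_progeny_table
#' @export
read_progeny_table <- function(path) {
  df <- read_tsv_commented(path)
  markers <- grep("^m[0-9]+$", names(df), value = TRUE)
  if (length(markers) < 2) {
    stop("file ", path, " must have at least two marker columns (m1, m2, ...)")
  }
  df <- df[markers]
  for (col in markers) {
    bad <- which(!df[[col]] %in% c(1L, 2L))
    if (length(bad) > 0) {
      stop("file ", path, ": column '", col, "', row ", bad[1L],
           " must be 1 or 2")
    }
  }
  attr(df, "parental_genotypes") <- list(rep(1L, length(markers)),
                                         rep(2L, length(markers)))
  df
}

#' Read a run configuration from JSON or YAML
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @param allowed Optional character vector of permitted keys; any other
#'   key is an error (guards against silently ignored typos).
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path, allowed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = ,
                yml = yaml::read_yaml(path),
                stop("unsupported config format '.", ext,
                     "' (use .json, .yaml or .yml)"))
  if (!is.list(cfg) || is.null(names(cfg)) || any(names(cfg) == "")) {
    stop("config file ", path, " must be a mapping of named parameters")
  }
  if (!is.null(allowed)) {
    unknown <- setdiff(names(cfg), allowed)
    if (length(unknown) > 0) {
      stop("config file ", path, " has unknown key(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  cfg
}
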