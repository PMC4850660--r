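#' Read referenced intensity pairs from a delimited text file
#'
#' Expects whitespace- or comma-separated columns: `I1 I2`,
#' `pair_index I1 I2` (the [write_pairs()] layout) or `h k l I1 I2`, with
#' optional `#`-prefixed comment lines and an optional
#' header row naming the columns.  When Miller indices are present, rows
#' are grouped by `(h, k, l)` — each group is one reflection and an
#' independent unit of work — preserving the original row order within a
#' group (the pairing is positional within a row, never across rows).
#' Without indices the whole file forms a single anonymous group.
#'
#' @param path file to read.
#' @param sep field separator: `""` (any whitespace, default) or `","`.
#' @return A named list of `"reflection_group"` objects, each a list with
#'   `hkl` (integer triple or `NULL`) and `pairs` (an
#'   [intensity_pairs()]).  Names are `"h k l"` or `"all"`.
#' @export
read_pairs <- function(path, sep = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("no data rows in ", path, call. = FALSE)
  split_row <- function(s) {
    if (sep == "") strsplit(trimws(s), "\\s+")[[1]]
    else trimws(strsplit(s, sep, fixed = TRUE)[[1]])
  }
  fields <- lapply(lines, split_row)
  nf <- lengths(fields)
  # optional header row: non-numeric tokens in the first row
  header <- suppressWarnings(anyNA(as.numeric(fields[[1]])))
  if (header) {
    fields <- fields[-1L]; lineno <- lineno[-1L]; nf <- nf[-1L]
    if (length(fields) == 0L) stop("no data rows in ", path, call. = FALSE)
  }
  width <- nf[1L]
  if (!width %in% c(2L, 3L, 5L))
    stop("line ", lineno[1L], ": expected 2 (I1 I2), 3 (pair_index I1 I2) ",
         "or 5 (h k l I1 I2) columns, found ", width, call. = FALSE)
  bad <- which(nf != width)
  if (length(bad))
    stop("line ", lineno[bad[1L]], ": ragged row (", nf[bad[1L]],
         " columns, expected ", width, ")", call. = FALSE)
  mat <- matrix(NA_real_, length(fields), width)
  for (i in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[i]]))
    if (anyNA(v))
      stop("line ", lineno[i], ": non-numeric value", call. = FALSE)
    mat[i, ] <- v
  }
  if (width <= 3L) {
    return(list(all = reflection_group(
      NULL, intensity_pairs(mat[, width - 1L], mat[, width]))))
  }
  key <- paste(mat[, 1], mat[, 2], mat[, 3])
  groups <- lapply(unique(key), function(k) {
    rows <- key == k
    reflection_group(as.integer(mat[which(rows)[1L], 1:3]),
                     intensity_pairs(mat[rows, 4], mat[rows, 5]))
  })
  names(groups) <- unique(key)
  groups
}

reflection_group <- function(hkl, pairs) {
  structure(list(hkl = hkl, pairs = pairs), class = "reflection_group")
}

#' Write intensity pairs as TSV
#'
#' Columns `pair_index`, `I1`, `I2`, preceded by `#` comment lines that
#' record the generating error model and seed when supplied, so a file is
#' self-describing.
#'
#' @param pairs an [intensity_pairs()] set.
#' @param path output file.
#' @param model optional [error_model()] recorded in the header.
#' @param seed optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path, model = NULL, seed = NULL) {
  pairs <- as_intensity_pairs(pairs)
  hdr <- character(0)
  if (!is.null(model))
    hdr <- c(hdr, sprintf(
      "# error_model: F1_true=%g F2_true=%g mu_sys=%g sigma_sys=%g sigma_ran=%g n_pairs=%d",
      model$F1_true, model$F2_true, model$mu_sys, model$sigma_sys,
      model$sigma_ran, model$n_pairs))
  if (!is.null(seed)) hdr <- c(hdr, sprintf("# seed: %d", as.integer(seed)))
  body <- sprintf("%d\t%.17g\t%.17g", seq_len(pairs$n), pairs$I1, pairs$I2)
  writeLines(c(hdr, "pair_index\tI1\tI2", body), path)
  invisible(path)
}

#' Read a YAML analysis configuration
#'
#' Sections `priors` (keys `amplitude_prior.type`,
#' `amplitude_prior.upper|mu|sigma`, `sigma_prior.mu_log`,
#' `sigma_prior.sigma_log`, `lkj_eta`) and `chain` (keys `n_iter`,
#' `burn_in`, `n_chains`, `adapt`); both sections and all keys are
#' optional and default to [prior_config()] / [chain_config()] values.
#'
#' @param path YAML file.
#' @return List with elements `priors` (a [prior_config()]) and `chain`
#'   (a [chain_config()]).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pr <- cfg$priors
  amp <- list(type = "uniform", upper = 1e8)
  if (!is.null(pr$amplitude_prior)) {
    ap <- pr$amplitude_prior
    amp <- list(type = ap$type %||% "uniform", upper = ap$upper,
                mu = ap$mu, sigma = ap$sigma)
    amp <- amp[!vapply(amp, is.null, logical(1))]
  }
  priors <- prior_config(
    amplitude = amp,
    sigma_mu_log = pr$sigma_prior$mu_log %||% 0,
    sigma_sigma_log = pr$sigma_prior$sigma_log %||% 1,
    lkj_eta = pr$lkj_eta %||% 1
  )
  ch <- cfg$chain
  chain <- chain_config(
    n_iter = ch$n_iter %||% 50000L,
    burn_in = ch$burn_in %||% 20000L,
    seed = ch$seed %||% 1L,
    adapt = ch$adapt %||% TRUE,
    n_chains = ch$n_chains %||% 2L
  )
  list(priors = priors, chain = chain)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit every reflection group in parallel
#'
#' Dispatches one [fit_pairs()] call per group to a worker pool.  Each
#' group's chain seed is derived deterministically from the master seed
#' and the group's position, so results are identical for any worker
#' count and adding groups never perturbs earlier ones.
#'
#' @param groups list of reflection groups as returned by [read_pairs()].
#' @param model_kind `"multivariate"` or `"univariate"`.
#' @param priors a [prior_config()].
#' @param chain a [chain_config()]; its seed is used as the master seed.
#' @param workers worker processes (forked; 1 = sequential).
#' @return Named list of [fit_pairs()] results, one per group.
#' @export
fit_groups <- function(groups, model_kind = "multivariate",
                       priors = prior_config(), chain = chain_config(),
                       workers = 1L) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  run_one <- function(i) {
    cfg <- chain
    cfg$seed <- derive_seed(chain$seed, i)
    fit_pairs(groups[[i]]$pairs, model_kind, priors, cfg)
  }
  idx <- seq_along(groups)
  fits <- if (workers > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(idx, run_one, mc.cores = workers)
  else lapply(idx, run_one)
  names(fits) <- names(groups)
  fits
}

#' Write posterior summaries for a set of fitted reflections
#'
#' TSV with columns `group`, `variable`, `median`, `hdi_low`, `hdi_high`,
#' `width`; optionally a JSON mirror holding the same records.
#'
#' @param fits named list of [fit_pairs()] results (as from
#'   [fit_groups()]).
#' @param path output TSV file.
#' @param json_path optional JSON output file.
#' @return The summary data frame, invisibly.
#' @export
write_summaries <- function(fits, path, json_path = NULL) {
  tab <- do.call(rbind, lapply(names(fits), function(g) {
    s <- summarize_posterior(fits[[g]])
    cbind(group = g, s)
  }))
  utils::write.table(tab[, c("group", "variable", "median", "hdi_low",
                             "hdi_high", "width")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(tab, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  invisible(tab)
}
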