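#' Read twin-pair counts from CSV
#'
#' Expects a CSV with header `zygosity,y11,yd,y00` and exactly one `MZ` row
#' and one `DZ` row.
#'
#' @param path Path to the counts file.
#' @return A list with `mz` and `dz` [twin_counts()] vectors.
#' @export
read_twin_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("zygosity", "y11", "yd", "y00")
  if (!all(need %in% names(df)))
    stop("counts file ", path, " must have columns ",
         paste(need, collapse = ","))
  df$zygosity <- toupper(trimws(df$zygosity))
  for (z in c("MZ", "DZ")) {
    k <- sum(df$zygosity == z)
    if (k != 1L)
      stop("counts file ", path, " must have exactly one ", z,
           " row, found ", k,
           if (k > 1L) paste0(" (rows ",
                              paste(which(df$zygosity == z) + 1L,
                                    collapse = ", "), ")"))
  }
  row_of <- function(z) {
    r <- df[df$zygosity == z, ]
    tryCatch(twin_counts(r$y11, r$yd, r$y00),
             error = function(e)
               stop("invalid ", z, " counts in ", path, " (line ",
                    which(df$zygosity == z) + 1L, "): ",
                    conditionMessage(e), call. = FALSE))
  }
  list(mz = row_of("MZ"), dz = row_of("DZ"))
}

#' Write twin-pair counts to CSV
#'
#' @param counts A list with `mz` and `dz` [twin_counts()] vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_twin_counts <- function(counts, path) {
  mz <- as_twin_counts(counts$mz)
  dz <- as_twin_counts(counts$dz)
  df <- data.frame(zygosity = c("MZ", "DZ"),
                   y11 = c(mz[["y11"]], dz[["y11"]]),
                   yd = c(mz[["yd"]], dz[["yd"]]),
                   y00 = c(mz[["y00"]], dz[["y00"]]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a simulation scenario from YAML or JSON
#'
#' Scenario files carry `pi`, `q_mz`, `q_dz`, `n_mz`, `n_dz`, and optionally
#' `seed`; the extension decides the parser (`.yaml`/`.yml` or `.json`).
#'
#' @param path Scenario file path.
#' @return A named list of scenario settings.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  sc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path)
  need <- c("pi", "q_mz", "q_dz", "n_mz", "n_dz")
  miss <- setdiff(need, names(sc))
  if (length(miss))
    stop("scenario file ", path, " is missing fields: ",
         paste(miss, collapse = ", "))
  sc
}

#' Fit the model from files and write all outputs
#'
#' Orchestrates a complete run: read counts, build the prior, Laplace
#' approximation, MH sampling, back-transformation, and summaries. Writes
#' `summary.csv`, `summary.json`, `chain.csv` (columns iteration, lambda,
#' mu_mz, mu_dz), and `manifest.json` (inputs, seed, hyperparameters,
#' acceptance rate, package version) into `out_dir`.
#'
#' @param counts_file CSV of counts (see [read_twin_counts()]).
#' @param out_dir Output directory, created if absent.
#' @param prevalence_study Optional string `"N_AFFECTED/N_TOTAL"` or numeric
#'   length-2 vector building an informative prevalence prior.
#' @param prior Base [twin_prior()] (overridden in `a1`, `a2` by
#'   `prevalence_study` if given).
#' @param n_iter,seed,burn_in,hpd_mass Passed to [twin_fit()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, the fitted `"twin_fit"` object.
#' @export
cmd_fit <- function(counts_file, out_dir, prevalence_study = NULL,
                    prior = twin_prior(), n_iter = 100000L, seed,
                    burn_in = 0L, hpd_mass = 0.95, quiet = FALSE) {
  counts <- read_twin_counts(counts_file)
  if (!is.null(prevalence_study)) {
    ps <- parse_prevalence_study(prevalence_study)
    prior <- prevalence_prior(ps[1], ps[2], prior)
  }
  say <- function(...) if (!quiet) message(...)
  say("fitting: ", sum(counts$mz), " MZ pairs, ", sum(counts$dz),
      " DZ pairs, ", n_iter, " iterations, seed ", seed)
  fit <- twin_fit(counts$mz, counts$dz, prior = prior, n_iter = n_iter,
                  burn_in = burn_in, seed = seed, hpd_mass = hpd_mass)
  say("acceptance rate: ", round(fit$acceptance_rate, 3))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- summary(fit)
  sdf <- cbind(quantity = rownames(s), as.data.frame(s))
  utils::write.csv(sdf, file.path(out_dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sdf, file.path(out_dir, "summary.json"),
                       dataframe = "rows", digits = NA)
  chain_df <- data.frame(iteration = seq_len(fit$n_iter), fit$chain$draws)
  utils::write.csv(chain_df, file.path(out_dir, "chain.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(
    package = "twinbayes",
    version = as.character(utils::packageVersion("twinbayes")),
    counts_file = counts_file,
    counts = list(mz = as.integer(counts$mz), dz = as.integer(counts$dz)),
    hyperparameters = fit$prior[c("a1", "a2", "b1", "b2", "g1", "g2")],
    n_iter = fit$n_iter, burn_in = fit$burn_in, seed = fit$seed,
    hpd_mass = fit$hpd_mass, acceptance_rate = fit$acceptance_rate)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("wrote summary.csv, summary.json, chain.csv, manifest.json to ",
      out_dir)
  invisible(fit)
}

parse_prevalence_study <- function(x) {
  if (is.character(x)) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("prevalence study must be given as 'N_AFFECTED/N_TOTAL'")
    x <- as.numeric(parts)
  }
  if (length(x) != 2L || anyNA(x))
    stop("prevalence study must be two counts: affected and total")
  x
}

#' Simulate a data set from a scenario file
#'
#' @param scenario_file YAML/JSON scenario (see [read_scenario()]).
#' @param out_file Output counts CSV path.
#' @param seed Seed override; defaults to the scenario's own seed.
#' @return Invisibly, the simulated counts list.
#' @export
cmd_simulate <- function(scenario_file, out_file, seed = NULL) {
  sc <- read_scenario(scenario_file)
  seed <- if (!is.null(seed)) seed else sc$seed
  if (is.null(seed)) stop("no seed in scenario file and none supplied")
  sim <- simulate_twin_data(sc$pi, sc$q_mz, sc$q_dz, sc$n_mz, sc$n_dz,
                            seed = seed)
  write_twin_counts(sim, out_file)
  invisible(sim)
}

#' Pool several counts files into one
#'
#' Reads each file and sums the count vectors per zygosity (equal-weight
#' pooling of historical studies).
#'
#' @param files Character vector of counts CSV paths.
#' @param out_file Output counts CSV path.
#' @return Invisibly, the pooled counts list.
#' @export
cmd_combine <- function(files, out_file) {
  if (length(files) < 1L) stop("at least one counts file is required")
  studies <- lapply(files, read_twin_counts)
  pooled <- pool_counts(studies)
  write_twin_counts(pooled, out_file)
  invisible(pooled)
}
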