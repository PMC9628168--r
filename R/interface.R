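#' Read and write three-level datasets as CSV
#'
#' The package's single dataset dialect: comma-separated, header row, UTF-8,
#' `.` decimal mark. Required columns: a level-3 id, a level-2 id and a
#' non-negative response; covariate columns are named by the caller. Ids may
#' be strings. `write_zab_data` / `read_zab_data` round-trip the typed
#' contents.
#'
#' @param path CSV file path.
#' @param response,level3,level2 column names.
#' @param zero_covariates,mean_covariates covariate columns per model part.
#' @param response_scale positive divisor applied to the response (the
#'   published analysis divides expenditure by 100).
#' @param center mean-center covariates?
#' @param data a [zab_data] object.
#' @return `read_zab_data`: a [zab_data]; `write_zab_data`: the path,
#'   invisibly.
#' @name zab_io
NULL

#' @rdname zab_io
#' @export
read_zab_data <- function(path, response = "y", level3 = "province",
                          level2 = "city",
                          zero_covariates = character(),
                          mean_covariates = character(),
                          response_scale = 1, center = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  zab_data(df, response = response, level3 = level3, level2 = level2,
           zero_covariates = zero_covariates, mean_covariates = mean_covariates,
           response_scale = response_scale, center = center)
}

#' @rdname zab_io
#' @export
write_zab_data <- function(data, path) {
  stopifnot(inherits(data, "zab_data"))
  covs <- unique(c(colnames(data$X1)[-1], colnames(data$X2)[-1]))
  df <- data.frame(province = data$prov_labels[data$prov],
                   city = data$city_labels[data$city],
                   y = data$y * data$response_scale)
  for (v in covs)
    df[[v]] <- if (v %in% colnames(data$X2)) data$X2[, v] else data$X1[, v]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[[i + 1L]], "--"))
      stop("flag --", key, " needs a value", call. = FALSE)
    out[[gsub("-", "_", key)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  out
}

flag <- function(flags, name, default = NULL, as = identity) {
  if (!is.null(flags[[name]])) as(flags[[name]]) else default
}

split_csv <- function(x) if (is.null(x) || !nzchar(x)) character() else
  strsplit(x, ",", fixed = TRUE)[[1]]

cli_family <- function(x) switch(x, zabp = "bp", zag = "gamma",
                                 stop("--family must be zabp or zag", call. = FALSE))

cli_fit_one <- function(data, fam, flags, out_dir, tag = fam) {
  control <- zab_control(
    n_chains = flag(flags, "chains", 2L, as.integer),
    n_iter = flag(flags, "iter", 20000L, as.integer),
    n_burnin = flag(flags, "burnin", 10000L, as.integer),
    thin = flag(flags, "thin", 10L, as.integer),
    seed = flag(flags, "seed", 1L, as.integer))
  model <- zab_model(family = fam)
  fit <- zab_fit(data, model, control = control)
  sm <- summary(fit)
  crit <- zab_criteria(fit)
  pool <- pooled_draws(fit)
  utils::write.csv(as.data.frame(pool),
                   file.path(out_dir, paste0("draws_", tag, ".csv")),
                   row.names = FALSE)
  utils::write.csv(sm, file.path(out_dir, paste0("summary_", tag, ".csv")),
                   row.names = FALSE)
  utils::write.csv(crit, file.path(out_dir, paste0("criteria_", tag, ".csv")),
                   row.names = FALSE)
  list(fit = fit, summary = sm, criteria = crit, control = control)
}

cli_manifest <- function(out_dir, command, flags, extra = list()) {
  manifest <- c(list(command = command, flags = flags,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Command-line interface
#'
#' Subcommands: `fit` (fit one model, write draws, a Table-2-style posterior
#' summary and the criteria), `simulate` (write a dataset plus the
#' generating truth from the simulation design), `study` (reduced
#' simulation study, write the metrics table), `compare` (fit the ZABP-RE
#' and ZAG-RE models on one dataset and write their criteria side by side).
#' Every run directory receives a `manifest.json` with the seed, settings,
#' acceptance rates and R-hats, sufficient to reproduce the run.
#'
#' Invoke from a shell as e.g.
#' `Rscript -e 'zabp::zab_cli()' fit --data d.csv --family zabp --seed 1
#' --out runs/fit1`.
#'
#' Common flags: `--data`, `--family` (`zabp` or `zag`),
#' `--zero-covariates a,b`, `--mean-covariates c,d`, `--chains`, `--iter`,
#' `--burnin`, `--thin`, `--seed`, `--response-scale`, `--out`; `simulate`
#' adds `--n`, `--n-i`, `--m-ij`; `study` adds `--reps`, `--n-values`;
#' `compare` takes `--families zabp,zag`.
#'
#' @param args character vector of command-line arguments; defaults to
#'   `commandArgs(trailingOnly = TRUE)`.
#' @return exit status, invisibly (0 on success, 1 on error).
#' @export
zab_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) < 1L)
      stop("usage: zab_cli <fit|simulate|study|compare> [--flags]", call. = FALSE)
    command <- args[[1]]
    flags <- parse_flags(args[-1])
    out_dir <- flag(flags, "out", ".")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

    read_from_flags <- function() {
      path <- flag(flags, "data")
      if (is.null(path)) stop("--data is required", call. = FALSE)
      read_zab_data(path,
                    response = flag(flags, "response", "y"),
                    level3 = flag(flags, "level3", "province"),
                    level2 = flag(flags, "level2", "city"),
                    zero_covariates = split_csv(flag(flags, "zero_covariates")),
                    mean_covariates = split_csv(flag(flags, "mean_covariates")),
                    response_scale = flag(flags, "response_scale", 1, as.numeric))
    }

    if (command == "fit") {
      fam <- cli_family(flag(flags, "family", "zabp"))
      data <- read_from_flags()
      res <- cli_fit_one(data, fam, flags, out_dir)
      cli_manifest(out_dir, "fit", flags, list(
        accept = res$fit$accept, max_rhat = max(res$summary$rhat, na.rm = TRUE),
        criteria = as.list(res$criteria)))
      message("fit written to ", out_dir)
    } else if (command == "simulate") {
      seed <- flag(flags, "seed", as = as.integer)
      if (is.null(seed)) stop("--seed is required for simulate", call. = FALSE)
      design <- sim_design(
        family = cli_family(flag(flags, "family", "zabp")),
        n = flag(flags, "n", 100L, as.integer),
        n_i = flag(flags, "n_i", 2L, as.integer),
        m_ij = flag(flags, "m_ij", 5L, as.integer))
      sim <- simulate_sim_design(design, seed)
      write_zab_data(sim$data, file.path(out_dir, "data.csv"))
      jsonlite::write_json(sim$truth[setdiff(names(sim$truth), c("p", "c"))],
                           file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      utils::write.csv(data.frame(level = c(rep("province", length(sim$truth$p)),
                                            rep("city", length(sim$truth$c))),
                                  effect = c(sim$truth$p, sim$truth$c)),
                       file.path(out_dir, "truth_re.csv"), row.names = FALSE)
      cli_manifest(out_dir, "simulate", flags,
                   list(zero_fraction = mean(sim$data$omega == 0)))
      message("dataset written to ", out_dir)
    } else if (command == "study") {
      seed <- flag(flags, "seed", as = as.integer)
      if (is.null(seed)) stop("--seed is required for study", call. = FALSE)
      design <- sim_design(family = cli_family(flag(flags, "family", "zabp")))
      study <- run_study(design,
        n_values = as.integer(split_csv(flag(flags, "n_values", "50,100"))),
        fit_families = vapply(split_csv(flag(flags, "families", "zabp")),
                              cli_family, ""),
        n_reps = flag(flags, "reps", 10L, as.integer),
        control = zab_control(n_iter = flag(flags, "iter", 4000L, as.integer),
                              n_burnin = flag(flags, "burnin", 2000L, as.integer),
                              thin = flag(flags, "thin", 10L, as.integer)),
        seed = seed)
      utils::write.csv(study$metrics, file.path(out_dir, "study_metrics.csv"),
                       row.names = FALSE)
      cli_manifest(out_dir, "study", flags)
      message("study metrics written to ", out_dir)
    } else if (command == "compare") {
      data <- read_from_flags()
      fams <- vapply(split_csv(flag(flags, "families", "zabp,zag")), cli_family, "")
      rows <- lapply(fams, function(fam)
        cbind(data.frame(model = fam), cli_fit_one(data, fam, flags, out_dir)$criteria))
      tab <- do.call(rbind, rows)
      utils::write.csv(tab, file.path(out_dir, "comparison.csv"), row.names = FALSE)
      cli_manifest(out_dir, "compare", flags)
      message("comparison written to ", out_dir)
    } else {
      stop("unknown subcommand: ", command, call. = FALSE)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
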