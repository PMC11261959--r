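# Study driver: replication experiments over simulated scenarios
# (model-comparison tables and entropy grids), plus dataset / report I/O.

#' Reconstruction defaults for the simulation studies
#'
#' Builds a [doc_params()] from study-level quantities: standardized trait
#' variances (additive-genetic and unique-environment variance proportions;
#' the shared-environment proportion is the remainder), causal coefficients,
#' class mean differences, and optional additive-genetic confounding.
#' Defaults give the two traits contrasting modes of inheritance
#' (X: A = 0.7, C = 0, E = 0.3; Y: A = 0.1, C = 0.6, E = 0.3), moderate
#' causal effects (b = 0.5) and mean-difference parameters of 0.5.
#'
#' The mean-difference convention: a value `delta` places the structural
#' intercepts of the X-causes-Y class at `+delta` and of the Y-causes-X
#' class at `-delta` on that trait, so the between-class separation in
#' observed means is `2 * delta` on the causally upstream trait and is
#' further amplified through the causal path on the downstream trait.  This
#' is the convention under which the high-separation benchmark condition
#' (`delta = 1.5` on both traits) produces near-perfect classification
#' (entropy close to 1).
#'
#' @param mean_diff_x,mean_diff_y class mean-difference parameters per trait
#'   (SD units; see Details).
#' @param b_xy,b_yx causal coefficients.
#' @param a2_x,a2_y additive-genetic variance proportions.
#' @param e2_x,e2_y unique-environment variance proportions.
#' @param r_a additive-genetic cross-trait confounding correlation.
#' @return A [doc_params()].
#' @export
study_params <- function(mean_diff_x = 0.5, mean_diff_y = 0.5,
                         b_xy = 0.5, b_yx = 0.5,
                         a2_x = 0.7, a2_y = 0.1,
                         e2_x = 0.3, e2_y = 0.3, r_a = 0) {
  c2_x <- 1 - a2_x - e2_x
  c2_y <- 1 - a2_y - e2_y
  if (c2_x < -1e-9 || c2_y < -1e-9)
    stop("variance proportions exceed 1: a2 + e2 must be <= 1 per trait")
  doc_params(a_x = sqrt(a2_x), c_x = sqrt(max(c2_x, 0)), e_x = sqrt(e2_x),
             a_y = sqrt(a2_y), c_y = sqrt(max(c2_y, 0)), e_y = sqrt(e2_y),
             b_xy = b_xy, b_yx = b_yx,
             nu_x_xy = mean_diff_x, nu_y_xy = mean_diff_y,
             nu_x_yx = -mean_diff_x, nu_y_yx = -mean_diff_y,
             r_a = r_a)
}

#' Replicated six-model comparison under one scenario
#'
#' For each replication: simulate a dataset from the scenario (with a
#' replication-specific seed derived from the root seed), fit all six model
#' families ([fit_model_set()]), and record df, -2LL and AIC.  Aggregates
#' the frequency with which each family attains the lowest AIC (AIC ties
#' closer than 0.01 are credited to the first family and counted in
#' `n_ties`) and each family's mean AIC gap to the per-replication best.
#'
#' @param scenario a [scenario_config()] (its own seed is ignored; seeds are
#'   derived from `seed`).
#' @param n_reps number of replications (>= 1).
#' @param seed integer root seed.
#' @param n_starts starting points per fitted family.
#' @return A `study_report_section` list: per-replication tables, AIC win
#'   frequencies, tie count and mean AIC gaps.
#' @export
run_model_comparison <- function(scenario, n_reps = 20, seed = 1,
                                 n_starts = 4) {
  stopifnot(inherits(scenario, "scenario_config"), n_reps >= 1)
  families <- c("mix4", "mix2", "doc_xy", "doc_yx", "doc_bidir", "cholesky")
  reps <- vector("list", n_reps)
  winners <- character(n_reps)
  n_ties <- 0L
  gaps <- matrix(NA_real_, n_reps, length(families),
                 dimnames = list(NULL, families))
  for (r in seq_len(n_reps)) {
    cfg <- scenario
    cfg$seed <- seed + 37L * r
    data <- simulate_dataset(cfg)
    ms <- fit_model_set(data, n_starts = n_starts, seed = seed + 37L * r + 11L)
    tab <- ms$table
    reps[[r]] <- tab
    ok <- !is.na(tab$aic)
    best <- min(tab$aic[ok])
    if (sum(tab$aic[ok] - best < 0.01) > 1L) n_ties <- n_ties + 1L
    winners[r] <- tab$model[ok][which.min(tab$aic[ok])]
    gaps[r, tab$model[ok]] <- tab$aic[ok] - best
  }
  win_freq <- vapply(families, function(f) mean(winners == f), numeric(1))
  structure(list(section = "model_comparison",
                 scenario_family = scenario$family,
                 n_reps = n_reps, seed = seed,
                 replications = reps,
                 winners = winners,
                 win_freq = win_freq,
                 n_ties = n_ties,
                 mean_aic_gap = colMeans(gaps, na.rm = TRUE)),
            class = "study_report_section")
}

#' @export
print.study_report_section <- function(x, ...) {
  cat(sprintf("study section: %s (%d replications)\n", x$section, x$n_reps))
  if (x$section == "model_comparison") {
    cat("AIC win frequencies:\n")
    print(round(x$win_freq, 3))
    cat("mean AIC gap to best:\n")
    print(round(x$mean_aic_gap, 2))
    if (x$n_ties) cat("ties (<0.01):", x$n_ties, "\n")
  } else if (x$section == "entropy_grid") {
    print(x$grid, row.names = FALSE)
  }
  invisible(x)
}

#' The entropy-grid cells of the simulation study
#'
#' Four sections, each varying one design quantity against the
#' reconstruction defaults of [study_params()]: phenotypic mean differences
#' per trait, causal effect sizes, the additive-genetic variance of trait Y
#' (with trait X fixed at 0.7), and additive-genetic confounding.
#'
#' @return A data frame of grid cells for [run_entropy_grid()].
#' @export
default_entropy_grid <- function() {
  rbind(
    data.frame(section = "mean_difference",
               mean_x = c(0.1, 0.5, 1.5, 0.5, 1.5),
               mean_y = c(0.1, 0.1, 0.1, 0.5, 1.5),
               b_xy = NA, b_yx = NA, a2_y = NA, r_a = NA),
    data.frame(section = "causal_effect", mean_x = NA, mean_y = NA,
               b_xy = c(0.1, 0.1, 0.1, 0.5, 0.8),
               b_yx = c(0.1, 0.5, 0.8, 0.5, 0.8),
               a2_y = NA, r_a = NA),
    data.frame(section = "heritability_y", mean_x = NA, mean_y = NA,
               b_xy = NA, b_yx = NA,
               a2_y = c(0.1, 0.3, 0.4, 0.5, 0.6), r_a = NA),
    data.frame(section = "confounding", mean_x = NA, mean_y = NA,
               b_xy = NA, b_yx = NA, a2_y = NA,
               r_a = c(0.1, 0.15, 0.2, 0.25, 0.3)))
}

grid_cell_params <- function(cell) {
  allowed <- c("section", "mean_x", "mean_y", "b_xy", "b_yx", "a2_y", "r_a")
  extra <- setdiff(names(cell), allowed)
  if (length(extra))
    stop("malformed grid cell '", cell$section %||% "?",
         "': unknown column(s) ", paste(extra, collapse = ", "))
  gv <- function(nm, default) {
    v <- cell[[nm]]
    if (is.null(v) || is.na(v)) default else v
  }
  study_params(mean_diff_x = gv("mean_x", 0.5), mean_diff_y = gv("mean_y", 0.5),
               b_xy = gv("b_xy", 0.5), b_yx = gv("b_yx", 0.5),
               a2_y = gv("a2_y", 0.1), r_a = gv("r_a", 0))
}

#' Mean classification entropy over a grid of simulation conditions
#'
#' For each grid cell: simulate equal-quarters 4-class mixture data at the
#' cell's parameters, obtain posterior class probabilities, and average the
#' relative entropy index over replications.  `entropy_mode = "fitted"`
#' (default) fits the 4-class mixture to each replication and uses its
#' posteriors (the extended r_a-free variant when the cell generates
#' confounding); `entropy_mode = "oracle"` evaluates posteriors at the
#' generating parameter values, which is fast and useful for trend checks.
#'
#' @param grid a data frame of cells as in [default_entropy_grid()].
#' @param n_reps replications per cell.
#' @param seed integer root seed.
#' @param n_mz,n_dz pairs per zygosity group.
#' @param entropy_mode `"fitted"` or `"oracle"`.
#' @param n_starts starting points per fit (fitted mode).
#' @return A `study_report_section` with the grid and its mean (and SD of)
#'   entropy per cell.
#' @export
run_entropy_grid <- function(grid = default_entropy_grid(), n_reps = 10,
                             seed = 1, n_mz = 2500, n_dz = 2500,
                             entropy_mode = c("fitted", "oracle"),
                             n_starts = 3) {
  entropy_mode <- match.arg(entropy_mode)
  stopifnot(is.data.frame(grid), n_reps >= 1)
  weights <- mixture_weights(c(0.25, 0.25, 0.25, 0.25))
  ent <- matrix(NA_real_, nrow(grid), n_reps)
  for (i in seq_len(nrow(grid))) {
    cell <- as.list(grid[i, , drop = FALSE])
    params <- grid_cell_params(cell)
    ra_free <- params$r_a != 0
    for (r in seq_len(n_reps)) {
      cfg <- scenario_config(n_mz, n_dz, params, weights, family = "mix4",
                             method = "quota",
                             seed = seed + 1009L * i + 37L * r)
      data <- simulate_dataset(cfg)
      post <- if (entropy_mode == "oracle") {
        posterior_probabilities(data, list(
          spec = model_spec("mix4"), params = params, weights = weights))
      } else {
        spec <- model_spec("mix4", confound_ra_free = ra_free)
        f <- fit_model(data, spec, n_starts = n_starts,
                       seed = seed + 1009L * i + 37L * r + 11L)
        posterior_probabilities(data, f)
      }
      ent[i, r] <- relative_entropy(post)
    }
  }
  out <- grid
  out$mean_entropy <- rowMeans(ent)
  out$sd_entropy <- apply(ent, 1, stats::sd)
  structure(list(section = "entropy_grid", n_reps = n_reps, seed = seed,
                 entropy_mode = entropy_mode, grid = out,
                 entropy = ent),
            class = "study_report_section")
}

#' Read a twin-pair dataset from CSV
#'
#' Expects a header `zygosity,x1,y1,x2,y2` (UTF-8); malformed rows are
#' rejected with their file line number.
#'
#' @param path path to a CSV file.
#' @return A [twin_data()] dataset.
#' @export
io_read_pairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("zygosity", "x1", "y1", "x2", "y2")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  bad <- which(!df$zygosity %in% c("MZ", "DZ"))
  if (length(bad))
    stop("unknown zygosity code '", df$zygosity[bad[1]], "' at line ",
         bad[1] + 1L, " of ", path)
  for (col in c("x1", "y1", "x2", "y2")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    nf <- which(!is.finite(v))
    if (length(nf))
      stop("non-finite value in column ", col, " at line ", nf[1] + 1L,
           " of ", path)
    df[[col]] <- v
  }
  twin_data(df)
}

#' Write a twin-pair dataset to CSV
#'
#' @param data a [twin_data()] dataset.
#' @param path output path.
#' @export
io_write_pairs <- function(data, path) {
  stopifnot(inherits(data, "twin_data"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Write a study report to JSON (or a table section to CSV)
#'
#' @param report a `study_report_section` or a list of them.
#' @param path output path.
#' @param format `"json"` (full report) or `"csv"` (tabular summary only).
#' @export
io_write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass_report(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    tab <- if (!is.null(report$grid)) report$grid
           else if (!is.null(report$win_freq))
             data.frame(model = names(report$win_freq),
                        win_freq = unname(report$win_freq),
                        mean_aic_gap = unname(report$mean_aic_gap))
           else stop("no tabular summary available for this report")
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

unclass_report <- function(x) {
  if (inherits(x, "study_report_section")) x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_report) else x
}

#' Read a scenario configuration from JSON or YAML
#'
#' Schema: `n_mz`, `n_dz`, `family`, `seed`, optional `method`, `params`
#' (named fields of [doc_params()]), optional `class_means` (lists `xy` and
#' `yx` of two phenotypic means, converted to structural intercepts), and
#' `weights` (`omega_mz`, optional `omega_dz`).
#'
#' @param path a `.json`, `.yaml` or `.yml` file.
#' @return A [scenario_config()].
#' @export
read_scenario <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  pars <- cfg$params %||% list()
  if (!is.null(cfg$class_means)) {
    b_xy <- pars$b_xy %||% 0; b_yx <- pars$b_yx %||% 0
    nus <- intercepts_for_class_means(unlist(cfg$class_means$xy),
                                      unlist(cfg$class_means$yx),
                                      b_xy, b_yx)
    pars[names(nus)] <- nus
  }
  params <- do.call(doc_params, pars)
  weights <- if (!is.null(cfg$weights))
    mixture_weights(unlist(cfg$weights$omega_mz),
                    unlist(cfg$weights$omega_dz %||% cfg$weights$omega_mz))
  scenario_config(cfg$n_mz, cfg$n_dz, params, weights,
                  family = cfg$family %||% "mix4",
                  method = cfg$method %||% "multinomial",
                  seed = cfg$seed %||% 1L)
}
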