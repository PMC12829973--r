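# stable content hash (rolling polynomial over the serialized object)
.plan_hash <- function(obj) {
  r <- as.integer(serialize(obj, NULL, version = 2))
  h <- 17
  for (b in r) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Define a replay experiment plan
#'
#' A plan fully determines an experiment: which protocol to run, its grid,
#' its scale-reduction factors and every seed. Serialized alongside the
#' results so a bundle can be audited and reproduced.
#'
#' Protocols:
#' \describe{
#'   \item{\code{population_grid}}{Population-model replay over an (R, F)
#'     grid for a given shape (success, speed, width maps).}
#'   \item{\code{spiking_grid}}{Connectivity scan (p_r, p_f) of a spiking
#'     variant via \code{\link{scanGrid}}.}
#'   \item{\code{delay_series}}{Spiking grids repeated over synaptic
#'     latencies.}
#'   \item{\code{membrane_grid}}{Leak-free fixed-in-degree networks with
#'     manually drawn membrane potentials, scanned over feedforward
#'     connectivity for each (mu, sigma).}
#' }
#'
#' @param experiment Protocol name (above).
#' @param base_seed Master seed.
#' @param stride Grid-thinning factor (1 = full grid).
#' @param n_networks,n_trials Replications at each spiking grid point.
#' @param outdir Output directory for \code{\link{runExperiment}}.
#' @param ... Protocol-specific settings (e.g. \code{R_values},
#'   \code{F_values}, \code{shape}, \code{q}; \code{variant},
#'   \code{pr_values}, \code{pf_values}, \code{tau_l_values};
#'   \code{mu_values}, \code{sigma_values}).
#' @return An object of class \code{"experiment_plan"}.
#' @export
experimentPlan <- function(experiment = c("population_grid", "spiking_grid",
                                          "delay_series", "membrane_grid"),
                           base_seed = 1L, stride = 1L,
                           n_networks = 3L, n_trials = 3L,
                           outdir = tempfile("replay_exp_"), ...) {
  experiment <- match.arg(experiment)
  plan <- c(list(experiment = experiment, base_seed = as.integer(base_seed),
                 stride = as.integer(stride), n_networks = as.integer(n_networks),
                 n_trials = as.integer(n_trials), outdir = outdir),
            list(...))
  class(plan) <- "experiment_plan"
  plan
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf("<experiment_plan> %s, seed %d, stride %d, outdir %s\n",
              x$experiment, x$base_seed, x$stride, x$outdir))
  invisible(x)
}

.thin <- function(v, stride) v[seq.int(1L, length(v), by = stride)]

.run_population_grid <- function(plan) {
  Rv <- .thin(plan$R_values %||% seq(0, 2, by = 0.1), plan$stride)
  Fv <- .thin(plan$F_values %||% seq(0, 2, by = 0.1), plan$stride)
  shape <- plan$shape %||% "rectangle"
  q <- plan$q %||% 10L
  grid <- expand.grid(R = Rv, F = Fv, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- populationParams(R = grid$R[i], F = grid$F[i], U = plan$U %||% 1,
                          shape = shape, x0 = plan$x0 %||% 0,
                          J = plan$J %||% ((plan$U %||% 1) - (plan$x0 %||% 0)),
                          q = q, t_max = plan$t_max %||% (50L * q))
    tr <- runPopulationReplay(p)
    data.frame(R = grid$R[i], F = grid$F[i], success = tr$success,
               S = tr$S, fwhm = trajectoryFWHM(tr))
  })
  do.call(rbind, rows)
}

.run_spiking_grid <- function(plan, tau_l = NULL) {
  cfg_args <- plan$config_args %||% list()
  if (!is.null(tau_l)) cfg_args$tau_l <- tau_l
  cfg <- do.call(networkConfig, c(list(variant = plan$variant %||% "minimal"),
                                  cfg_args))
  scanGrid(cfg,
           pr_values = .thin(plan$pr_values %||% seq(0, 0.16, by = 0.02),
                             plan$stride),
           pf_values = .thin(plan$pf_values %||% seq(0, 0.16, by = 0.02),
                             plan$stride),
           pairs = plan$pairs %||% NULL,
           n_networks = plan$n_networks, n_trials = plan$n_trials,
           base_seed = plan$base_seed)
}

.run_delay_series <- function(plan) {
  tls <- plan$tau_l_values %||% c(1, 4)
  rows <- lapply(tls, function(tl) {
    g <- .run_spiking_grid(plan, tau_l = tl)
    g$tau_l <- tl
    g
  })
  do.call(rbind, rows)
}

.run_membrane_grid <- function(plan) {
  mus <- plan$mu_values %||% c(-50.9, -51.9, -52.9)
  sigmas <- plan$sigma_values %||% c(0, 0.5, 1)
  cfg <- networkConfig(plan$variant %||% "minimal", leak_free = TRUE,
                       connectivity_mode = "fixed_in_degree")
  rows <- list()
  for (mu in mus) for (sg in sigmas) {
    g <- scanGrid(cfg,
                  pr_values = .thin(plan$pr_values %||% c(0), plan$stride),
                  pf_values = .thin(plan$pf_values %||% seq(0.04, 0.2, by = 0.02),
                                    plan$stride),
                  n_networks = plan$n_networks, n_trials = plan$n_trials,
                  base_seed = plan$base_seed,
                  init = function(cn, seed) initMembraneGaussian(cn, mu, sg, seed))
    g$mu <- mu; g$sigma <- sg
    rows[[length(rows) + 1L]] <- g
  }
  do.call(rbind, rows)
}

#' Run an experiment plan and write its result bundle
#'
#' Dispatches on the plan's protocol, writes \code{grid.csv} and a
#' \code{manifest.json} embedding the plan, its content hash and the seed.
#' Idempotent: re-running a plan whose manifest hash matches an existing
#' complete bundle returns the stored results without recomputation.
#'
#' @param plan An \code{"experiment_plan"}.
#' @return The result data frame (invisibly also written to
#'   \code{plan$outdir}).
#' @export
runExperiment <- function(plan) {
  stopifnot(inherits(plan, "experiment_plan"))
  hash <- .plan_hash(unclass(plan)[setdiff(names(plan), "outdir")])
  dir.create(plan$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(plan$outdir, "manifest.json")
  grid_path <- file.path(plan$outdir, "grid.csv")
  if (file.exists(manifest_path) && file.exists(grid_path)) {
    man <- jsonlite::read_json(manifest_path)
    if (identical(man$hash, hash) && isTRUE(man$complete))
      return(utils::read.csv(grid_path))
  }
  res <- switch(plan$experiment,
    population_grid = .run_population_grid(plan),
    spiking_grid = .run_spiking_grid(plan),
    delay_series = .run_delay_series(plan),
    membrane_grid = .run_membrane_grid(plan))
  utils::write.csv(res, grid_path, row.names = FALSE)
  jsonlite::write_json(
    list(hash = hash, experiment = plan$experiment,
         base_seed = plan$base_seed, complete = TRUE,
         plan = unclass(plan)[setdiff(names(plan),
                                      c("outdir", "pairs", "config_args"))]),
    manifest_path, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  res
}
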