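#' Configuration for the synthetic cytometry feeding experiment
#'
#' Emulates the structure of a flow-cytometric bacterivory assay: an algal
#' population with log-normal forward scatter (FSC), chlorophyll red
#' fluorescence and baseline green fluorescence; bacterial tracer-prey
#' (FLB) events with low scatter/red and bright green; an ingestion process
#' in which a fraction `f(t) = f_max * (1 - exp(-rate * t))` of algal cells
#' has ingested at least one FLB by time `t` (hours), each fed cell gaining
#' the summed green of a zero-truncated Poisson number of FLB; and an
#' extracellular-fluorophore background `b0 * exp(-beta * t)` added to the
#' green signal of every event after FLB addition (the photobleaching
#' decline of the dissolved dye).  Fixed (`CT_PFA`) and heat-killed-prey
#' (`DTAF`) treatments force the fed fraction to zero.
#'
#' All intensities are arbitrary units.  Defaults describe a
#' nutrient-limited grazer at desk scale: 10,000 algal events per read
#' (mirroring the dilute-culture cap on events per subsample), `f_max`
#' 0.3, t = 0..3 h at 1-h intervals, triplicate subsamples.
#'
#' @param n_algal_events,n_flb_events events per read.
#' @param algal_fsc,algal_red,algal_green,flb_fsc,flb_red,flb_green
#'   `c(meanlog, sdlog)` log-normal parameters.
#' @param f_max,rate fed-fraction trajectory parameters (`f_max` in
#'   `[0, 1]`, `rate` per hour; the trajectory is non-decreasing).
#' @param lambda_ingest Poisson mean of ingested-FLB count (conditioned
#'   >= 1).
#' @param increment_green `c(meanlog, sdlog)` of the per-FLB green gain.
#' @param b0 background green added at t0; `beta` its photobleach decay
#'   rate (per hour).
#' @param timepoints assay time points in hours (must include 0 and 3).
#' @param treatments subset of `CT`, `DTAF`, `CT_PFA`.
#' @param replicates subsamples per treatment.
#' @param seed RNG seed.
#' @return A validated `facs_config` list.
#' @export
facs_config <- function(n_algal_events = 10000L, n_flb_events = 10000L,
                        algal_fsc = c(meanlog = log(500), sdlog = 0.3),
                        algal_red = c(meanlog = log(800), sdlog = 0.4),
                        algal_green = c(meanlog = log(20), sdlog = 0.25),
                        flb_fsc = c(meanlog = log(30), sdlog = 0.4),
                        flb_red = c(meanlog = log(3), sdlog = 0.5),
                        flb_green = c(meanlog = log(300), sdlog = 0.3),
                        f_max = 0.3, rate = 1.0,
                        lambda_ingest = 1.5,
                        increment_green = c(meanlog = log(400), sdlog = 0.3),
                        b0 = 10, beta = 0.5,
                        timepoints = 0:3,
                        treatments = c("CT", "DTAF", "CT_PFA"),
                        replicates = 3L, seed = 1L) {
  treatments <- match.arg(treatments, c("CT", "DTAF", "CT_PFA"),
                          several.ok = TRUE)
  for (nm in c("algal_fsc", "algal_red", "algal_green", "flb_fsc",
               "flb_red", "flb_green", "increment_green")) {
    v <- get(nm)
    if (length(v) != 2 || v[2] < 0)
      stopf("%s must be c(meanlog, sdlog) with sdlog >= 0", nm)
  }
  if (f_max < 0 || f_max > 1) stopf("f_max must lie in [0, 1]")
  if (rate < 0) stopf("rate must be >= 0")
  if (b0 < 0 || beta < 0) stopf("b0 and beta must be >= 0")
  if (lambda_ingest <= 0) stopf("lambda_ingest must be > 0")
  if (!all(c(0, 3) %in% timepoints)) stopf("timepoints must include 0 and 3")
  if (n_algal_events < 1) stopf("need at least one algal event")
  structure(list(n_algal_events = as.integer(n_algal_events),
                 n_flb_events = as.integer(n_flb_events),
                 algal_fsc = algal_fsc, algal_red = algal_red,
                 algal_green = algal_green, flb_fsc = flb_fsc,
                 flb_red = flb_red, flb_green = flb_green,
                 f_max = f_max, rate = rate,
                 lambda_ingest = lambda_ingest,
                 increment_green = increment_green,
                 b0 = b0, beta = beta,
                 timepoints = sort(unique(timepoints)),
                 treatments = treatments,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "facs_config")
}

# fed fraction at time t (hours)
fed_fraction <- function(cfg, t, treatment) {
  if (treatment %in% c("DTAF", "CT_PFA")) return(rep(0, length(t)))
  cfg$f_max * (1 - exp(-cfg$rate * t))
}

rlnorm2 <- function(n, par) rlnorm(n, par[[1]], par[[2]])

# zero-truncated Poisson
rtpois <- function(n, lambda) {
  qpois(runif(n, dpois(0, lambda), 1), lambda)
}

event_table <- function(fsc, red, green, strain, treatment, nutrient,
                        replicate, timepoint, truth = NULL) {
  stopifnot(all(fsc > 0), all(red > 0), all(green > 0))
  tab <- data.frame(fsc = fsc, red = red, green = green)
  attr(tab, "meta") <- list(strain = strain, treatment = treatment,
                            nutrient = nutrient, replicate = replicate,
                            timepoint = timepoint)
  attr(tab, "truth") <- truth
  class(tab) <- c("event_table", "data.frame")
  tab
}

#' Metadata of an event table
#' @param tab an `event_table`.
#' @export
event_meta <- function(tab) attr(tab, "meta")

#' Generate a synthetic cytometry run
#'
#' For every treatment and replicate: a pre-inoculation baseline read
#' (algae only, no FLB background) and one read per time point containing
#' algal events (a planted `Bernoulli(f(t))` subset carries ingestion green
#' increments) mixed with FLB events, all post-inoculation events sharing
#' the photobleaching background `b0 * exp(-beta t)` on the green channel.
#' FLB-only reads at t0 and t3 (per treatment) support the fluorescence
#' stability check.  Ground-truth event labels (`is_algal`, `fed`) ride on
#' every table for oracle tests.  Fully reproducible from the seed.
#'
#' @param cfg a [facs_config()].
#' @param strain,nutrient metadata labels.
#' @return A `facs_run`: `tables` (named list, `baseline` plus `t0`..`t3`
#'   per treatment x replicate), `flb_only` (per treatment, t0 and t3),
#'   `config`.
#' @export
generate_facs_run <- function(cfg = facs_config(), strain = "strain_1",
                              nutrient = "limited") {
  stopifnot(inherits(cfg, "facs_config"))
  set.seed(cfg$seed)
  tables <- list()
  for (trt in cfg$treatments) {
    for (rep_i in seq_len(cfg$replicates)) {
      n <- cfg$n_algal_events
      key <- function(tp) sprintf("%s_rep%d_%s", trt, rep_i, tp)
      # baseline: algae only, pre-FLB
      tables[[key("baseline")]] <- event_table(
        rlnorm2(n, cfg$algal_fsc), rlnorm2(n, cfg$algal_red),
        rlnorm2(n, cfg$algal_green),
        strain, trt, nutrient, rep_i, "baseline",
        truth = data.frame(is_algal = rep(TRUE, n), fed = rep(FALSE, n)))
      for (t in cfg$timepoints) {
        f_t <- fed_fraction(cfg, t, trt)
        fed <- runif(n) < f_t
        green <- rlnorm2(n, cfg$algal_green)
        if (any(fed)) {
          k <- rtpois(sum(fed), cfg$lambda_ingest)
          green[fed] <- green[fed] + vapply(k, function(ki)
            sum(rlnorm2(ki, cfg$increment_green)), numeric(1))
        }
        bg <- cfg$b0 * exp(-cfg$beta * t)
        nf <- cfg$n_flb_events
        tab <- event_table(
          fsc = c(rlnorm2(n, cfg$algal_fsc), rlnorm2(nf, cfg$flb_fsc)),
          red = c(rlnorm2(n, cfg$algal_red), rlnorm2(nf, cfg$flb_red)),
          green = c(green, rlnorm2(nf, cfg$flb_green)) + bg,
          strain, trt, nutrient, rep_i, sprintf("t%d", t),
          truth = data.frame(is_algal = rep(c(TRUE, FALSE), c(n, nf)),
                             fed = c(fed, rep(FALSE, nf))))
        tables[[key(sprintf("t%d", t))]] <- tab
      }
    }
  }
  flb_only <- list()
  for (trt in cfg$treatments) {
    for (tp in c(0, 3)) {
      nf <- cfg$n_flb_events
      flb_only[[sprintf("%s_t%d", trt, tp)]] <- event_table(
        rlnorm2(nf, cfg$flb_fsc), rlnorm2(nf, cfg$flb_red),
        rlnorm2(nf, cfg$flb_green),
        strain, trt, nutrient, NA_integer_, sprintf("t%d", tp),
        truth = data.frame(is_algal = rep(FALSE, nf), fed = rep(FALSE, nf)))
    }
  }
  structure(list(tables = tables, flb_only = flb_only, config = cfg,
                 strain = strain, nutrient = nutrient),
            class = "facs_run")
}

#' @export
print.facs_run <- function(x, ...) {
  cat(sprintf("<facs_run> %s (%s): %d event tables, %d FLB-only tables\n",
              x$strain, x$nutrient, length(x$tables), length(x$flb_only)))
  invisible(x)
}

#' Write a cytometry run as CSV event tables with a JSON sidecar
#'
#' One CSV per read (`fsc`, `red`, `green`) and a `run.json` manifest with
#' metadata, seed, and the planted ground truth per table.
#'
#' @param run a [generate_facs_run()] result.
#' @param dir output directory.
#' @export
write_facs_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(strain = run$strain, nutrient = run$nutrient,
               seed = run$config$seed, tables = list())
  for (nm in names(run$tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(as.data.frame(run$tables[[nm]]), p, row.names = FALSE)
    meta$tables[[nm]] <- c(event_meta(run$tables[[nm]]),
                           list(file = basename(p),
                                n_fed_truth = sum(attr(run$tables[[nm]],
                                                       "truth")$fed)))
  }
  jsonlite::write_json(meta, file.path(dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
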