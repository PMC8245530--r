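#' Gating specification for algal populations
#'
#' Algal events are selected on chlorophyll red fluorescence and forward
#' scatter.  Red threshold policies: `"cluster"` (default) splits log(red)
#' with a deterministic two-means (centers initialised at the extremes) and
#' gates at the geometric mean of the two cluster centers, which is robust
#' to unbalanced algal/bacterial mixtures; `"quantile"` gates at a fixed
#' quantile of the mixed red distribution; `"absolute"` gates at a fixed
#' value.
#'
#' @param red_policy threshold policy.
#' @param red_value quantile probability (for `"quantile"`) or absolute
#'   threshold (for `"absolute"`).
#' @param fsc_bounds closed lower/upper forward-scatter bounds.
#' @return A `gate_spec` list.
#' @export
gate_spec <- function(red_policy = c("cluster", "quantile", "absolute"),
                      red_value = NULL, fsc_bounds = c(0, Inf)) {
  red_policy <- match.arg(red_policy)
  if (red_policy == "quantile") {
    red_value <- red_value %||% 0.5
    if (red_value <= 0 || red_value >= 1) stopf("quantile must lie in (0, 1)")
  }
  if (red_policy == "absolute") {
    if (is.null(red_value) || red_value <= 0)
      stopf("absolute policy needs a positive threshold")
  }
  if (length(fsc_bounds) != 2 || fsc_bounds[1] >= fsc_bounds[2] ||
      fsc_bounds[1] < 0)
    stopf("fsc_bounds must be an increasing non-negative pair")
  structure(list(red_policy = red_policy, red_value = red_value,
                 fsc_bounds = fsc_bounds),
            class = "gate_spec")
}

# deterministic 1-D two-means on log(red): Lloyd iterations from the
# extreme values.  If the two centers are well separated relative to the
# within-cluster spread the threshold is their geometric mean; otherwise
# the distribution is treated as a single (algal) population and the gate
# keeps every event, which also makes gating idempotent.
red_cluster_threshold <- function(red) {
  lx <- log(red)
  c1 <- min(lx); c2 <- max(lx)
  if (c2 - c1 < 1e-12) return(exp(c1))
  g2 <- logical(length(lx))
  for (it in seq_len(100)) {
    mid <- (c1 + c2) / 2
    g2 <- lx > mid
    if (!any(g2) || all(g2)) break
    n1 <- mean(lx[!g2]); n2 <- mean(lx[g2])
    if (abs(n1 - c1) < 1e-12 && abs(n2 - c2) < 1e-12) break
    c1 <- n1; c2 <- n2
  }
  s1 <- if (sum(!g2) > 1) sd(lx[!g2]) else 0
  s2 <- if (sum(g2) > 1) sd(lx[g2]) else 0
  if ((c2 - c1) < 2 * (s1 + s2)) return(min(red))   # unimodal: keep all
  exp((c1 + c2) / 2)
}

#' Gate algal events
#'
#' @param tab an `event_table`.
#' @param gate a [gate_spec()].
#' @return List `mask` (logical per event), `cells_total`, `red_threshold`.
#'   An empty gate is an error (flagged for the replicate upstream).
#' @export
gate_algae <- function(tab, gate = gate_spec()) {
  if (nrow(tab) == 0) stopf("empty event table")
  thr <- switch(gate$red_policy,
                cluster = red_cluster_threshold(tab$red),
                quantile = quantile(tab$red, gate$red_value, names = FALSE),
                absolute = gate$red_value)
  mask <- tab$red >= thr & tab$fsc >= gate$fsc_bounds[1] &
    tab$fsc <= gate$fsc_bounds[2]
  if (!any(mask)) stopf("gate selects no events")
  list(mask = mask, cells_total = sum(mask), red_threshold = thr)
}

#' Baseline green-fluorescence threshold (GF_prior)
#'
#' The maximum (default) or a configured quantile of the gated green
#' values in the pre-inoculation baseline read; cells later exceeding it
#' are counted as fed.
#'
#' @param baseline baseline `event_table` (pre-FLB).
#' @param gate a [gate_spec()].
#' @param policy `"max"` or `"quantile"`.
#' @param q quantile probability when `policy = "quantile"`.
#' @return GF_prior (green, arbitrary units).
#' @export
gf_prior <- function(baseline, gate = gate_spec(), policy = c("max", "quantile"),
                     q = 0.999) {
  policy <- match.arg(policy)
  g <- gate_algae(baseline, gate)
  greens <- baseline$green[g$mask]
  if (policy == "max") max(greens) else quantile(greens, q, names = FALSE)
}

#' Fed-cell percentage at one time point
#'
#' `cells_fed` counts gated events with green strictly exceeding GF_prior
#' (ties count as not fed); `per_fed = cells_fed / cells_total * 100`.
#'
#' @param tab an `event_table`.
#' @param gate a [gate_spec()].
#' @param gf_prior threshold from [gf_prior()] on the same culture's
#'   baseline.
#' @return List `cells_total`, `cells_fed`, `per_fed`.
#' @export
per_fed <- function(tab, gate = gate_spec(), gf_prior) {
  g <- gate_algae(tab, gate)
  if (g$cells_total == 0) stopf("no gated cells")
  fed <- sum(tab$green[g$mask] > gf_prior)
  list(cells_total = g$cells_total, cells_fed = fed,
       per_fed = 100 * fed / g$cells_total)
}

#' Change in fed percentage over the incubation
#'
#' `per_delta = per_fed(t3) - per_fed(t0)`; the t0 subtraction removes the
#' background jump caused by extracellular fluorophores added with the
#' FLB.  Negative values are legal (photobleaching of that background can
#' outweigh slow feeding) and are reported as-is.
#'
#' @param series named numeric vector of per_fed values with at least
#'   `t0` and `t3`.
#' @return per_delta (percentage points).
#' @export
per_delta <- function(series) {
  if (!all(c("t0", "t3") %in% names(series)))
    stopf("per_fed series must contain t0 and t3")
  unname(series[["t3"]] - series[["t0"]])
}

#' FLB fluorescence stability check
#'
#' Two-sided Student's t-test on the mean green fluorescence of FLB-only
#' reads at t0 vs t3; the prey label is considered stable when
#' `p > alpha`.
#'
#' @param flb_t0,flb_t3 FLB-only `event_table`s.
#' @param alpha level.
#' @return List `p`, `stable`, `degenerate` (TRUE when both inputs are
#'   constant and the test is undefined).
#' @export
flb_stability <- function(flb_t0, flb_t3, alpha = 0.05) {
  x <- flb_t0$green; y <- flb_t3$green
  if (sd(x) == 0 && sd(y) == 0)
    return(list(p = NA_real_, stable = NA, degenerate = TRUE))
  tt <- t.test(x, y, var.equal = TRUE)
  list(p = tt$p.value, stable = tt$p.value > alpha, degenerate = FALSE)
}

#' Quantify a whole cytometry run
#'
#' For every treatment x replicate: GF_prior from that replicate's
#' baseline, per_fed at every time point, and per_delta.  Replicates whose
#' gate is empty are flagged and skipped with a warning.
#'
#' @param run a [generate_facs_run()] result (or a compatible list of
#'   event tables).
#' @param gate a [gate_spec()].
#' @return A `feeding_result` data.frame: strain, nutrient, treatment,
#'   replicate, gf_prior, cells_total_t*, per_fed_t*, per_delta.
#' @export
feeding_results <- function(run, gate = gate_spec()) {
  cfg <- run$config
  rows <- list()
  for (trt in cfg$treatments) {
    for (rep_i in seq_len(cfg$replicates)) {
      key <- function(tp) sprintf("%s_rep%d_%s", trt, rep_i, tp)
      res <- try({
        gf <- gf_prior(run$tables[[key("baseline")]], gate)
        series <- sapply(cfg$timepoints, function(t) {
          pf <- per_fed(run$tables[[key(sprintf("t%d", t))]], gate, gf)
          pf$per_fed
        })
        names(series) <- sprintf("t%d", cfg$timepoints)
        totals <- sapply(cfg$timepoints, function(t)
          gate_algae(run$tables[[key(sprintf("t%d", t))]], gate)$cells_total)
        row <- data.frame(strain = run$strain, nutrient = run$nutrient,
                          treatment = trt, replicate = rep_i,
                          gf_prior = gf, stringsAsFactors = FALSE)
        for (i in seq_along(series)) {
          row[[paste0("cells_total_", names(series)[i])]] <- totals[i]
          row[[paste0("per_fed_", names(series)[i])]] <- series[i]
        }
        row$per_delta <- per_delta(series)
        row
      }, silent = TRUE)
      if (inherits(res, "try-error")) {
        warnf("replicate %s/%d flagged: %s", trt, rep_i,
              attr(res, "condition")$message)
        next
      }
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("feeding_result", "data.frame")
  out
}

#' Summarise feeding results over replicates
#'
#' Mean and standard deviation of per_delta per strain x nutrient x
#' treatment (triplicate subsamples in the default design).
#'
#' @param results a [feeding_results()] data.frame.
#' @return Data.frame with n, mean_per_delta, sd_per_delta.
#' @export
summarize_feeding <- function(results) {
  sp <- split(results$per_delta,
              list(results$strain, results$nutrient, results$treatment),
              drop = TRUE, sep = "\r")
  keys <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
  data.frame(strain = keys[, 1], nutrient = keys[, 2], treatment = keys[, 3],
             n = lengths(sp),
             mean_per_delta = vapply(sp, mean, numeric(1)),
             sd_per_delta = vapply(sp, sd, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
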