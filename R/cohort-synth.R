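#' Specification of a synthetic AVF cohort
#'
#' Describes two outflow groups (High/Low) with per-variable normal
#' locations and scales, truncated at physical bounds when sampled. The
#' default means and SDs are the High/Low group statistics of the packaged
#' 17-fistula table, so the generator emulates that cohort's distributions
#' at arbitrary sample size.
#'
#' @param n_per_group records per group (>= 2).
#' @param group_means named list `High`/`Low` of named numeric vectors over
#'   the anatomical variables (`fa_diameter_mm`, `fa_curvature`,
#'   `dv_diameter_mm`, `dv_curvature`, `anastomosis_angle_deg`).
#' @param group_sds same shape as `group_means`, all > 0.
#' @param flow_mean,flow_sd named vectors (`High`, `Low`): location/scale of
#'   venous outflow (ml/min) per group.
#' @param flow_link monotone function applied to the latent outflow score
#'   before noise is added (default identity).
#' @param seed integer: one seed reproduces the whole table.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 20,
                        group_means = NULL, group_sds = NULL,
                        flow_mean = c(High = 1618, Low = 630),
                        flow_sd = c(High = 550, Low = 250),
                        flow_link = identity,
                        seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (is.null(group_means) || is.null(group_sds)) {
    tab <- load_avf_cohort()
    hi <- tab$outflow_category == "High"
    vars <- c("fa_diameter_mm", "fa_curvature", "dv_diameter_mm",
              "dv_curvature", "anastomosis_angle_deg")
    pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
    gm <- list(High = vapply(tab[hi, vars], mean, 0),
               Low = vapply(tab[!hi, vars], mean, 0))
    gs <- list(High = vapply(tab[hi, vars], pop_sd, 0),
               Low = vapply(tab[!hi, vars], pop_sd, 0))
    if (is.null(group_means)) group_means <- gm
    if (is.null(group_sds)) group_sds <- gs
  }
  stopifnot(identical(names(group_means$High), names(group_means$Low)),
            identical(names(group_means$High), names(group_sds$High)))
  if (any(unlist(group_sds) <= 0)) stop("group_sds must be > 0")
  if (any(flow_sd <= 0)) stop("flow_sd must be > 0")
  structure(list(n_per_group = as.integer(n_per_group),
                 group_means = group_means, group_sds = group_sds,
                 flow_mean = flow_mean, flow_sd = flow_sd,
                 flow_link = flow_link, seed = as.integer(seed)),
            class = "cohort_spec")
}

variable_bounds <- function(v) {
  switch(v,
         fa_diameter_mm = , dv_diameter_mm = c(0.5, 15),
         fa_curvature = , dv_curvature = c(1e-4, 0.2),
         anastomosis_angle_deg = c(1, 179),
         venous_outflow_ml_min = c(0, Inf),
         c(-Inf, Inf))
}

rtruncnorm_reject <- function(n, mean, sd, lo, hi, max_tries = 100L) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (k in seq_len(max_tries)) {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lo && x <= hi) { out[i] <- x; ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf("no admissible draw in %d attempts (mean %.3g, sd %.3g, bounds [%.3g, %.3g])",
                   max_tries, mean, sd, lo, hi))
  }
  out
}

#' Generate a synthetic cohort table
#'
#' Draws each anatomical variable per group from its truncated normal,
#' assigns venous outflow through the monotone flow link plus noise
#' (truncated at 0), and fills the categorical columns by sampling the
#' fixture's composition. The output reproduces the packaged table's column
#' schema, with the generating group kept in `latent_group`; the
#' `outflow_category` column is re-derived from the sampled outflow via the
#' >= 1000 ml/min rule, so it can disagree with the generating group, as in
#' real cohorts.
#'
#' @param spec a [cohort_spec()].
#' @return `data.frame` with the fixture schema plus `latent_group`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_per_group
  vars <- names(spec$group_means$High)
  rows <- list()
  for (grp in c("High", "Low")) {
    dat <- as.data.frame(lapply(vars, function(v) {
      b <- variable_bounds(v)
      rtruncnorm_reject(n, spec$group_means[[grp]][[v]],
                        spec$group_sds[[grp]][[v]], b[1], b[2])
    }))
    names(dat) <- vars
    latent <- spec$flow_link(rep(spec$flow_mean[[grp]], n))
    q <- latent + stats::rnorm(n, 0, spec$flow_sd[[grp]])
    q <- pmax(q, 0)
    dat$venous_outflow_ml_min <- q
    dat$latent_group <- grp
    rows[[grp]] <- dat
  }
  dat <- do.call(rbind, rows)
  nn <- nrow(dat)
  out <- data.frame(
    patient_id = sprintf("synth_%03d", seq_len(nn)),
    fistula_type = sample(c("RCF", "BCF", "BBF"), nn, replace = TRUE,
                          prob = c(10, 6, 1) / 17),
    side = sample(c("left", "right"), nn, replace = TRUE, prob = c(15, 2) / 17),
    outcome = sample(c("S", "U"), nn, replace = TRUE, prob = c(13, 4) / 17),
    venous_outflow_ml_min = dat$venous_outflow_ml_min,
    outflow_category = NA_character_,
    stringsAsFactors = FALSE)
  for (v in vars) out[[v]] <- dat[[v]]
  out$outflow_category <- dichotomize_flow(out)
  out$latent_group <- dat$latent_group
  rownames(out) <- NULL
  out
}
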