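# Gage repeatability & reproducibility: crossed two-factor ANOVA with
# interaction, expected-mean-squares variance components, and the
# conventional %-study-variation summary with 10%/30% acceptability bands.

#' Validate a measurement table
#'
#' A measurement-system study table: one row per score, with the measured
#' item (`part`), the scorer (`operator`), the replicate index and the
#' value (here, percent above threshold). The design must be fully crossed
#' and balanced.
#'
#' @param data Data frame with columns `part`, `operator`, `replicate`,
#'   `value`.
#' @return The validated data frame, classed `measurement_table`.
#' @export
measurement_table <- function(data) {
  need <- c("part", "operator", "replicate", "value")
  if (!all(need %in% names(data))) {
    .stop_gelquant(paste("measurement table needs columns:",
                         paste(need, collapse = ", ")),
                   "gelquant_design_error")
  }
  data$part <- factor(data$part)
  data$operator <- factor(data$operator)
  counts <- table(data$part, data$operator)
  if (nlevels(data$part) < 2L || nlevels(data$operator) < 2L) {
    .stop_gelquant("need >= 2 parts and >= 2 operators",
                   "gelquant_design_error")
  }
  if (any(counts == 0L) || length(unique(as.vector(counts))) != 1L) {
    .stop_gelquant("design must be crossed and balanced (equal replicates per part x operator cell)",
                   "gelquant_design_error")
  }
  if (counts[1L] < 2L) {
    .stop_gelquant("need >= 2 replicates per cell", "gelquant_design_error")
  }
  structure(data, class = c("measurement_table", "data.frame"))
}

#' Read a measurement table from CSV
#'
#' @param path Long-format CSV with columns `part`, `operator`,
#'   `replicate`, `value`.
#' @return A [measurement_table()].
#' @export
read_measurement_table <- function(path) {
  measurement_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Gage R&R crossed ANOVA
#'
#' Two-factor crossed ANOVA with interaction; variance components by the
#' expected-mean-squares solution. When the part x operator interaction is
#' not supported (F-test p > `pool_p`), it is pooled into repeatability.
#' Repeatability is the error (equipment/within-scorer) component;
#' reproducibility is the operator component plus any unpooled interaction.
#' Percentage figures are percent of total study variation on the SD
#' scale, so total %GRR obeys the quadrature identity
#' `sqrt(repeatability^2 + reproducibility^2)`.
#'
#' @param data A [measurement_table()] (or coercible data frame).
#' @param pool_p Interaction pooling threshold on the F-test p-value
#'   (default 0.25, standard MSA practice).
#' @return An object of class `gage_rr`: list with `varcomp` (data frame:
#'   component, variance, sd, pct_study_var), `classification`,
#'   `interaction_pooled`, `truncated` (components clipped at zero),
#'   `anova` (mean squares), and the design sizes.
#' @export
gage_rr <- function(data, pool_p = 0.25) {
  data <- measurement_table(as.data.frame(data))
  p <- nlevels(data$part)
  o <- nlevels(data$operator)
  r <- nrow(data) / (p * o)

  fit <- stats::aov(value ~ part * operator, data = data)
  an <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  ms <- stats::setNames(an[["Mean Sq"]], rownames(an))
  ms_p <- ms[["part"]]
  ms_o <- ms[["operator"]]
  ms_po <- ms[["part:operator"]]
  ms_e <- ms[["Residuals"]]

  p_int <- if (ms_e > 0) {
    stats::pf(ms_po / ms_e, (p - 1) * (o - 1), p * o * (r - 1),
              lower.tail = FALSE)
  } else NA_real_
  pooled <- is.na(p_int) || p_int > pool_p
  if (pooled) {
    df_po <- (p - 1) * (o - 1)
    df_e <- p * o * (r - 1)
    ms_e <- (ms_po * df_po + ms_e * df_e) / (df_po + df_e)
    var_po <- 0
    var_o <- (ms_o - ms_e) / (p * r)
    var_p <- (ms_p - ms_e) / (o * r)
  } else {
    var_po <- (ms_po - ms_e) / r
    var_o <- (ms_o - ms_po) / (p * r)
    var_p <- (ms_p - ms_po) / (o * r)
  }
  var_e <- ms_e

  raw <- c(repeatability = var_e, operator = var_o,
           interaction = var_po, part = var_p)
  truncated <- names(raw)[raw < 0]
  comp <- pmax(raw, 0)

  var_reprod <- comp[["operator"]] + comp[["interaction"]]
  var_grr <- comp[["repeatability"]] + var_reprod
  var_total <- var_grr + comp[["part"]]

  # a total variance at numerical-noise level means the scores carry no
  # variation to apportion; flag rather than report meaningless ratios
  degenerate <- var_total <= 1e-16 * (mean(data$value^2) + 1)
  if (degenerate) {
    comp[] <- 0
    var_reprod <- var_grr <- var_total <- 0
  }
  sd_total <- sqrt(var_total)

  pct <- function(v) if (sd_total > 0) 100 * sqrt(v) / sd_total else NA_real_
  varcomp <- data.frame(
    component = c("repeatability", "reproducibility", "total_grr",
                  "part_to_part", "total"),
    variance = c(comp[["repeatability"]], var_reprod, var_grr,
                 comp[["part"]], var_total),
    sd = sqrt(c(comp[["repeatability"]], var_reprod, var_grr,
                comp[["part"]], var_total)),
    pct_study_var = c(pct(comp[["repeatability"]]), pct(var_reprod),
                      pct(var_grr), pct(comp[["part"]]), pct(var_total)),
    stringsAsFactors = FALSE)

  classification <- if (degenerate) "degenerate"
                    else classify_grr(varcomp$pct_study_var[3L])

  structure(list(varcomp = varcomp, classification = classification,
                 interaction_pooled = pooled, interaction_p = p_int,
                 truncated = truncated,
                 anova = data.frame(term = rownames(an),
                                    mean_sq = an[["Mean Sq"]],
                                    df = an[["Df"]]),
                 n_parts = p, n_operators = o, n_replicates = r),
            class = "gage_rr")
}

#' @export
print.gage_rr <- function(x, ...) {
  cat(sprintf("<gage_rr> %d parts x %d operators x %g replicates\n",
              x$n_parts, x$n_operators, x$n_replicates))
  vc <- x$varcomp
  vc$variance <- signif(vc$variance, 4)
  vc$sd <- signif(vc$sd, 4)
  vc$pct_study_var <- round(vc$pct_study_var, 2)
  print(vc, row.names = FALSE)
  cat(sprintf("  interaction pooled: %s | classification: %s\n",
              x$interaction_pooled, x$classification))
  if (length(x$truncated)) {
    cat("  negative variance estimate(s) truncated to 0:",
        paste(x$truncated, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify a total Gage R&R percentage
#'
#' Conventional measurement-system guidelines: total %GRR under 10% of
#' study variation is acceptable, 10% up to (excluding) 30% is acceptable
#' under conditions, and 30% or more is unacceptable.
#'
#' @param x Total %GRR (numeric) or a [gage_rr()] result.
#' @return `"acceptable"`, `"conditional"`, or `"unacceptable"`.
#' @export
classify_grr <- function(x) {
  if (inherits(x, "gage_rr")) x <- x$varcomp$pct_study_var[3L]
  if (is.na(x)) return("degenerate")
  if (x < 10) "acceptable" else if (x < 30) "conditional" else "unacceptable"
}

#' Combine repeatability and reproducibility in quadrature
#'
#' Because %-study-variation figures live on the SD scale, the total Gage
#' R&R percentage is the quadrature sum of its two components.
#'
#' @param repeatability,reproducibility Percent study variation.
#' @return Total %GRR.
#' @export
grr_quadrature <- function(repeatability, reproducibility) {
  sqrt(repeatability^2 + reproducibility^2)
}

#' Simulate a crossed measurement study
#'
#' Draws scores from the additive crossed model
#' `value = mean + part_i + operator_j + (part:operator)_ij + error`, with
#' independent Gaussian effects of the given SDs. Used to verify that
#' [gage_rr()] recovers known variance components.
#'
#' @param n_parts,n_operators,n_replicates Design sizes.
#' @param sd_part,sd_operator,sd_interaction,sd_error Effect SDs.
#' @param mean Grand mean of the scores.
#' @param seed Integer seed.
#' @return A [measurement_table()].
#' @export
simulate_scores <- function(n_parts = 10, n_operators = 2,
                            n_replicates = 10, sd_part = 10,
                            sd_operator = 0, sd_interaction = 0,
                            sd_error = 1, mean = 50, seed = 1L) {
  .with_seed(seed, {
    parts <- stats::rnorm(n_parts, sd = sd_part)
    ops <- stats::rnorm(n_operators, sd = sd_operator)
    inter <- matrix(stats::rnorm(n_parts * n_operators, sd = sd_interaction),
                    n_parts, n_operators)
    grid <- expand.grid(replicate = seq_len(n_replicates),
                        operator = seq_len(n_operators),
                        part = seq_len(n_parts))
    grid$value <- mean + parts[grid$part] + ops[grid$operator] +
      inter[cbind(grid$part, grid$operator)] +
      stats::rnorm(nrow(grid), sd = sd_error)
    measurement_table(grid[, c("part", "operator", "replicate", "value")])
  })
}
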