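#' Multi-environment RCBD ANOVA with variance components and GCV
#'
#' Fits the randomized-complete-block multi-environment model
#' `y_ijk = mu + t_i + b_j(i) + g_k + (gt)_ik + e_ijk`
#' (environment and block-within-environment fixed, genotype and
#' genotype-by-environment random) by least squares with sequential
#' (Type-I) sums of squares in that model order. Variance components are
#' solved from the expected mean squares:
#' `E[MS_GxE] = s2_e + b_eff * s2_ge` and
#' `E[MS_G] = s2_e + b_eff * s2_ge + e * b_eff * s2_g`,
#' with `b_eff = N / (n_geno * n_env)` the effective replication (exact for
#' balanced data; the documented approximation when block counts differ
#' between environments). The genetic coefficient of variation is
#' `GCV = 100 * sigma_g / mu`.
#'
#' @param trial data.frame with columns `genotype`, `environment`, `block`,
#'   `trait`, `value` (long format; blocks nested within environments).
#' @param trait trait name to analyse.
#' @return list with the ANOVA table (`anova`, data.frame of df/SS/MS),
#'   `varcomp` (raw `s2_g`, `s2_ge`, `s2_e`, possibly negative),
#'   `varcomp_clamped`, `mu`, `gcv_percent` (from the clamped `s2_g`), and
#'   `negative_component` flag.
#' @export
rcbd_anova_gcv <- function(trial, trait) {
  stopifnot(all(c("genotype", "environment", "block", "trait", "value")
                %in% names(trial)))
  d <- trial[trial$trait == trait, , drop = FALSE]
  if (nrow(d) == 0L) stop("no data for trait '", trait, "'")
  d$genotype <- factor(d$genotype)
  d$environment <- factor(d$environment)
  d$block <- factor(paste(d$environment, d$block, sep = "/"))
  ng <- nlevels(d$genotype); ne <- nlevels(d$environment)
  if (ng < 2L || ne < 2L) stop("need >= 2 genotypes and >= 2 environments")
  if (any(table(d$genotype, d$environment, d$block) > 1L))
    stop("duplicated (genotype, environment, block) observation")
  fit <- stats::aov(value ~ environment + block %in% environment +
                      genotype + genotype:environment, data = d)
  at <- stats::anova(fit)
  rn <- rownames(at)
  get_row <- function(pat) at[grep(pat, rn)[1], ]
  ms_g  <- get_row("^genotype$")[["Mean Sq"]]
  ms_ge <- get_row("^environment:genotype$|^genotype:environment$")[["Mean Sq"]]
  ms_e  <- at["Residuals", "Mean Sq"]
  if (is.na(ms_e) || at["Residuals", "Df"] == 0)
    stop("no error degrees of freedom: genotype x environment cells ",
         "are unreplicated")
  b_eff <- nrow(d) / (ng * ne)
  s2_ge <- (ms_ge - ms_e) / b_eff
  s2_g  <- (ms_g - ms_ge) / (ne * b_eff)
  s2_e  <- ms_e
  raw <- c(s2_g = s2_g, s2_ge = s2_ge, s2_e = s2_e)
  clamped <- pmax(raw, 0)
  mu <- mean(d$value)
  list(anova = data.frame(term = rn, df = at$Df, ss = at$`Sum Sq`,
                          ms = at$`Mean Sq`, stringsAsFactors = FALSE),
       varcomp = raw, varcomp_clamped = clamped, mu = mu,
       gcv_percent = 100 * sqrt(clamped[["s2_g"]]) / mu,
       negative_component = any(raw < 0))
}

#' Descriptive trait summary per region and pooled
#'
#' Mean, minimum, maximum and the coefficient-of-variation-style dispersion
#' (100 * sd / mean) per region and over all samples.
#'
#' @param values named numeric vector: id -> trait value.
#' @param partition named vector id -> region label.
#' @return data.frame with one row per region plus `ALL`.
#' @export
subpopulation_summary <- function(values, partition) {
  if (length(values) == 0L) stop("no values")
  regions <- sort(unique(unname(partition[names(values)])))
  one <- function(v, label) {
    data.frame(region = label, n = length(v), mean = mean(v),
               min = min(v), max = max(v),
               cv_percent = if (mean(v) == 0) NA_real_
                            else 100 * stats::sd(v) / mean(v),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(regions, function(r)
    one(values[names(values)[partition[names(values)] == r]], r))
  rows[[length(rows) + 1L]] <- one(values, "ALL")
  out <- do.call(rbind, rows)
  out$cv_percent[is.na(out$cv_percent) & out$n == 1L] <- 0
  out
}
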