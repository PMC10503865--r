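# Cohort statistics: covariate-adjusted metabolite screening with
# heteroscedasticity-robust Wald tests, fractional regression of relative
# abundances, compositional log-ratio tests, flux-group comparisons, and
# Benjamini-Hochberg multiple-testing correction. All model fitting goes
# through lm()/glm(); robust covariances come from the sandwich estimators.

robust_wald <- function(fit, terms, hc_type = "HC3") {
  V <- sandwich::vcovHC(fit, type = hc_type)
  b <- stats::coef(fit)
  keep <- intersect(terms, names(b)[!is.na(b)])
  if (length(keep) == 0) return(list(stat = NA_real_, df = 0, p = NA_real_))
  W <- drop(t(b[keep]) %*% solve(V[keep, keep, drop = FALSE]) %*% b[keep])
  list(stat = W, df = length(keep),
       p = stats::pchisq(W, df = length(keep), lower.tail = FALSE))
}

robust_coef <- function(fit, term, hc_type = "HC3") {
  b <- stats::coef(fit)
  if (!term %in% names(b) || is.na(b[[term]])) {
    return(list(estimate = NA_real_, se = NA_real_, stat = NA_real_,
                p = NA_real_))
  }
  V <- sandwich::vcovHC(fit, type = hc_type)
  se <- sqrt(V[term, term])
  z <- b[[term]] / se
  list(estimate = b[[term]], se = se, stat = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Screen urine metabolites for group association
#'
#' For each metabolite with at least `min_nonzero` non-zero measurements
#' (zeros are treated as missing — a zero NMR quantification does not imply
#' absence), the log concentration is regressed on the study-group factor
#' plus age, sex and BMI by least squares. The group factor is tested
#' jointly by a Wald chi-square with heteroscedasticity-robust (HC)
#' covariance, the case-vs-control contrast is reported separately, and
#' Benjamini-Hochberg q-values are computed across the screened metabolites.
#'
#' @param concentrations long tibble (sample, metabolite, concentration),
#'   concentrations >= 0 with 0 = missing.
#' @param metadata tibble (sample, group, age, sex, bmi); `group`'s first
#'   factor level (or `"control"` when present) is the reference.
#' @param case_level group level contrasted against the reference, default
#'   `"AD"`.
#' @param min_nonzero minimum fraction of non-zero measurements, default 0.5.
#' @param hc_type robust covariance flavour, default `"HC3"`.
#' @return Tibble per metabolite: n_used, estimate/se/p for the case
#'   contrast, the joint group Wald statistic and p, q-values, and an
#'   `excluded` flag (prevalence filter) with excluded rows retained.
#' @export
screen_metabolites <- function(concentrations, metadata, case_level = "AD",
                               min_nonzero = 0.5, hc_type = "HC3") {
  stopifnot(all(c("sample", "metabolite", "concentration") %in%
                  names(concentrations)),
            all(c("sample", "group", "age", "sex", "bmi") %in% names(metadata)))
  if (any(concentrations$concentration < 0)) {
    stop("negative concentrations", call. = FALSE)
  }
  dat <- dplyr::inner_join(concentrations, metadata, by = "sample")
  lv <- unique(dat$group)
  ref <- if ("control" %in% lv) "control" else sort(lv)[1]
  dat$group <- stats::relevel(factor(dat$group), ref = ref)
  case_term <- paste0("group", case_level)
  rows <- dat |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::group_map(function(d, key) {
      nz <- d$concentration > 0
      prev <- mean(nz)
      if (prev < min_nonzero) {
        return(tibble::tibble(metabolite = key$metabolite, n_used = sum(nz),
                              prevalence = prev, excluded = TRUE,
                              estimate = NA_real_, se = NA_real_,
                              p_case = NA_real_, wald_stat = NA_real_,
                              wald_df = NA_integer_, p_group = NA_real_))
      }
      dd <- d[nz, ]
      fit <- stats::lm(log(concentration) ~ group + age + sex + bmi, data = dd)
      grp_terms <- grep("^group", names(stats::coef(fit)), value = TRUE)
      jw <- robust_wald(fit, grp_terms, hc_type)
      cc <- robust_coef(fit, case_term, hc_type)
      tibble::tibble(metabolite = key$metabolite, n_used = nrow(dd),
                     prevalence = prev, excluded = FALSE,
                     estimate = cc$estimate, se = cc$se, p_case = cc$p,
                     wald_stat = jw$stat, wald_df = as.integer(jw$df),
                     p_group = jw$p)
    }) |>
    dplyr::bind_rows()
  rows$q_case <- NA_real_
  rows$q_group <- NA_real_
  inc <- !rows$excluded
  rows$q_case[inc] <- bh_fdr(rows$p_case[inc])
  rows$q_group[inc] <- bh_fdr(rows$p_group[inc])
  rows
}

#' Fractional regression of relative abundances on group
#'
#' For each species present (non-zero) in at least `min_prevalence` of the
#' samples, the relative abundance in [0, 1] is modelled by a logit-link
#' quasi-binomial GLM (fractional regression) on group plus APOE4 carriage,
#' fitted by iteratively reweighted least squares, with sandwich robust
#' standard errors on the group coefficient. Non-converged fits are flagged,
#' not raised.
#'
#' @param abundances relative `abundance_table`.
#' @param metadata tibble (sample, group, apoe4).
#' @param case_level group level contrasted against the reference.
#' @param min_prevalence presence filter, default 0.5.
#' @param hc_type robust covariance flavour.
#' @return Tibble per species: prevalence, excluded, estimate (log-odds
#'   scale), se, stat, p, q, converged.
#' @export
fractional_regression <- function(abundances, metadata, case_level = "AD",
                                  min_prevalence = 0.5, hc_type = "HC3") {
  stopifnot(inherits(abundances, "abundance_table"))
  if (!identical(attr(abundances, "mode"), "relative")) {
    stop("abundances must be in relative mode (values in [0,1])", call. = FALSE)
  }
  sp <- abundance_species(abundances)
  vals <- as.matrix(abundances[, sp, drop = FALSE])
  if (any(vals < 0 | vals > 1)) {
    stop("relative abundances outside [0, 1]", call. = FALSE)
  }
  meta <- metadata[match(abundances$sample, metadata$sample), ]
  lv <- unique(meta$group)
  ref <- if ("control" %in% lv) "control" else sort(lv)[1]
  grp <- stats::relevel(factor(meta$group), ref = ref)
  case_term <- paste0("grp", case_level)
  rows <- purrr::map(sp, function(s) {
    y <- vals[, s]
    prev <- mean(y > 0)
    if (prev < min_prevalence) {
      return(tibble::tibble(species = s, prevalence = prev, excluded = TRUE,
                            estimate = NA_real_, se = NA_real_,
                            stat = NA_real_, p = NA_real_, converged = NA))
    }
    fit <- suppressWarnings(
      stats::glm(y ~ grp + apoe4, family = stats::quasibinomial("logit"),
                 data = data.frame(y = y, grp = grp, apoe4 = meta$apoe4)))
    cc <- robust_coef(fit, case_term, hc_type)
    tibble::tibble(species = s, prevalence = prev, excluded = FALSE,
                   estimate = cc$estimate, se = cc$se, stat = cc$stat,
                   p = cc$p, converged = fit$converged)
  }) |> dplyr::bind_rows()
  rows$q <- NA_real_
  rows$q[!rows$excluded] <- bh_fdr(rows$p[!rows$excluded])
  rows
}

#' Compositional log-ratio test between groups
#'
#' Per sample, the log ratio of the summed counts of an "increased" species
#' set over a "decreased" species set (a pseudocount guards zero sums), then
#' a Welch two-sample t-test of the log ratio between groups.
#'
#' @param counts an `abundance_table` in counts mode.
#' @param metadata tibble (sample, group).
#' @param up_set,down_set non-empty species sets.
#' @param case_level group compared against the rest.
#' @param pseudocount added to the summed counts of each set, default 0.5.
#' @return list with `samples` (tibble sample, group, log_ratio) and `test`
#'   (tibble estimate, statistic, df, p) from Welch's t-test.
#' @export
log_ratio_test <- function(counts, metadata, up_set, down_set,
                           case_level = "AD", pseudocount = 0.5) {
  stopifnot(inherits(counts, "abundance_table"))
  if (length(up_set) == 0 || length(down_set) == 0) {
    stop("up_set and down_set must be non-empty", call. = FALSE)
  }
  sp <- abundance_species(counts)
  missing <- setdiff(c(up_set, down_set), sp)
  if (length(missing) > 0) {
    stop("species not in table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  up <- rowSums(counts[, up_set, drop = FALSE]) + pseudocount
  dn <- rowSums(counts[, down_set, drop = FALSE]) + pseudocount
  if (any(dn <= 0) || any(up <= 0)) {
    stop("non-positive set totals; use a positive pseudocount", call. = FALSE)
  }
  meta <- metadata[match(counts$sample, metadata$sample), ]
  lr <- log(up / dn)
  grp <- ifelse(meta$group == case_level, case_level, "other")
  a <- lr[grp == case_level]; b <- lr[grp != case_level]
  test <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate case (e.g. identical up and down sets): no variance to test
    tibble::tibble(estimate = mean(a) - mean(b), statistic = 0,
                   df = NA_real_, p = if (mean(a) == mean(b)) 1 else 0)
  } else {
    tt <- stats::t.test(a, b)
    tibble::tibble(estimate = unname(diff(rev(tt$estimate))),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value)
  }
  list(samples = tibble::tibble(sample = counts$sample, group = meta$group,
                                log_ratio = unname(lr)),
       test = test)
}

#' Compare secretion fluxes between groups
#'
#' Ordinary least squares of one flux per sample on group, APOE4 and sex,
#' with heteroscedasticity-robust standard errors on the group coefficient.
#' Covariate columns that are constant (rank deficient) are dropped with a
#' warning.
#'
#' @param fluxes tibble (sample, flux).
#' @param metadata tibble (sample, group, apoe4, sex).
#' @param case_level group level contrasted against the reference.
#' @param hc_type robust covariance flavour.
#' @return One-row tibble: estimate, se, stat, p, conf.low, conf.high, n.
#' @export
compare_fluxes <- function(fluxes, metadata, case_level = "AD",
                           hc_type = "HC3") {
  stopifnot(all(c("sample", "flux") %in% names(fluxes)))
  dat <- dplyr::inner_join(fluxes, metadata, by = "sample")
  lv <- unique(dat$group)
  ref <- if ("control" %in% lv) "control" else sort(lv)[1]
  dat$group <- stats::relevel(factor(dat$group), ref = ref)
  covars <- c("apoe4", "sex")
  use <- covars[vapply(covars, function(v) length(unique(dat[[v]])) > 1,
                       logical(1))]
  dropped <- setdiff(covars, use)
  if (length(dropped) > 0) {
    warning("constant covariate(s) dropped: ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  fml <- stats::reformulate(c("group", use), response = "flux")
  fit <- stats::lm(fml, data = dat)
  cc <- robust_coef(fit, paste0("group", case_level), hc_type)
  ci <- cc$estimate + c(-1, 1) * stats::qnorm(0.975) * cc$se
  tibble::tibble(term = paste0("group", case_level), estimate = cc$estimate,
                 se = cc$se, stat = cc$stat, p = cc$p,
                 conf.low = ci[1], conf.high = ci[2], n = nrow(dat))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; a thin, name-stable wrapper
#' around `p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector in [0, 1] (NAs propagated).
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values outside [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}
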