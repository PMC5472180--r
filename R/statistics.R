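#' @importFrom lme4 lmer lmerControl fixef
NULL

# Derived analysis covariates shared by all models.
prep_model_data <- function(table) {
  d <- as.data.frame(table)
  if (!is.null(d$age)) d$age5 <- d$age / 5
  if (!is.null(d$subtype)) d$lacunar <- as.numeric(d$subtype == "lacunar")
  if (!is.null(d$t10_ms)) d$t10_s <- d$t10_ms / 1000
  d
}

focus_var <- c(age = "age5", fazekas = "fazekas", subtype = "lacunar")
adjust_var <- c(hypertension = "hypertension", map = "map",
                pulse_pressure = "pulse_pressure", smoker = "smoker",
                t10 = "t10_s", sinus = "sinus", age = "age5",
                fazekas = "fazekas", subtype = "lacunar")

new_coeftab <- function(df, n_obs = NA_integer_, n_patients = NA_integer_) {
  rownames(df) <- NULL
  structure(df, n_obs = n_obs, n_patients = n_patients,
            class = c("bbb_coeftab", "data.frame"))
}

#' @export
print.bbb_coeftab <- function(x, digits = 3, ...) {
  cat("Coefficients (beta x 10^3, Wald 95% CI):\n")
  d <- as.data.frame(x)
  d$estimate <- d$estimate * 1e3
  d$ci95_low <- d$ci95_low * 1e3
  d$ci95_high <- d$ci95_high * 1e3
  d$se <- NULL
  print(format(d, digits = digits), row.names = FALSE)
  invisible(x)
}

wald_rows <- function(est, se, term, stratum = NA_character_) {
  z <- est / se
  data.frame(term = term, stratum = stratum, estimate = est, se = se,
             ci95_low = est - qnorm(0.975) * se,
             ci95_high = est + qnorm(0.975) * se,
             p_value = 2 * pnorm(-abs(z)),
             stringsAsFactors = FALSE)
}

assert_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

lmer_wald <- function(formula, data, pattern) {
  fit <- lmer(formula, data = data, REML = TRUE,
              control = lmerControl(calc.derivs = FALSE))
  fe <- fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  keep <- grep(pattern, names(fe))
  list(fit = fit, est = fe[keep], se = se[keep])
}

#' Mixed model of leakage slopes across tissues and covariates
#'
#' The inferential core: a linear mixed model of per-patient, per-tissue
#' enhancement slopes with a random patient intercept, yielding per-tissue
#' coefficients for the covariate of interest. Following the
#' one-interaction-family-at-a-time convention (simultaneous fitting of all
#' tissue interactions is rarely supported at cohort sizes of interest),
#' each `focus` covariate (age per 5-year increment, Fazekas score per
#' point, stroke subtype as lacunar vs cortical with negative = lower in
#' lacunar) is fitted in its own model with a per-tissue interaction, while
#' the other focus covariates and the adjustment set (hypertension, mean
#' arterial pressure, pulse pressure, smoking, pre-contrast tissue T1,
#' sagittal-sinus intravascular signal) enter as main effects. Inference is
#' Wald with normal approximation; no multiple-testing correction is
#' applied; fits are complete-case with the dropped-row count attached.
#'
#' @param table a [build_slope_table()] long table (or compatible
#'   data.frame).
#' @param focus interaction families to fit, subset of
#'   `c("age", "fazekas", "subtype")`.
#' @param adjust adjustment covariates, subset of `c("hypertension",
#'   "map", "pulse_pressure", "smoker", "t10", "sinus")`.
#' @param tissues tissue strata to model; default the classical six
#'   compartments present in the table.
#' @param single_stratum set TRUE to explicitly fit one tissue stratum by
#'   ordinary least squares (no random intercept is identifiable from one
#'   row per patient).
#' @return a `bbb_coeftab` with one row per focus term x tissue stratum.
#' @export
fit_leakage_model <- function(table,
                              focus = c("age", "fazekas", "subtype"),
                              adjust = c("hypertension", "map",
                                         "pulse_pressure", "smoker",
                                         "t10", "sinus"),
                              tissues = NULL,
                              single_stratum = FALSE) {
  focus <- match.arg(focus, several.ok = TRUE)
  d <- prep_model_data(table)
  if (is.null(tissues))
    tissues <- intersect(c("nawm", "dgm", "csf", "wmh", "index_infarct",
                           "old_infarct"), unique(d$tissue))
  d <- d[d$tissue %in% tissues, ]
  vars <- unique(c("slope", unname(focus_var[focus]), unname(adjust_var[adjust])))
  d <- d[complete.cases(d[, vars]), ]
  n_pat <- length(unique(d$patient))
  if (n_pat < 2L)
    stop("at least 2 patients are required: the patient random intercept is undefined")
  if (length(tissues) < 2L && !single_stratum)
    stop("fewer than 2 tissue strata; pass single_stratum = TRUE to fit one stratum")
  if (nrow(d) < length(tissues) + length(vars) + 1L)
    stop("too few rows to fit the model")
  d$tissue <- factor(d$tissue, levels = tissues)
  adj <- unname(adjust_var[adjust])
  out <- list()
  for (f in focus) {
    fv <- focus_var[[f]]
    others <- unname(focus_var[setdiff(focus, f)])
    if (length(tissues) >= 2L) {
      rhs <- paste(c("0", "tissue", paste0("tissue:", fv), others, adj),
                   collapse = " + ")
      X <- model.matrix(as.formula(paste("~", rhs)), d)
      assert_full_rank(X)
      form <- as.formula(paste("slope ~", rhs, "+ (1 | patient)"))
      w <- lmer_wald(form, d, paste0(":", fv, "$"))
      strat <- sub(paste0("^tissue(.*):", fv, "$"), "\\1", names(w$est))
      rows <- wald_rows(unname(w$est), unname(w$se), term = f, stratum = strat)
    } else {
      rhs <- paste(c(fv, others, adj), collapse = " + ")
      X <- model.matrix(as.formula(paste("~", rhs)), d)
      assert_full_rank(X)
      fit <- lm(as.formula(paste("slope ~", rhs)), data = d)
      est <- coef(fit)[fv]
      se <- sqrt(diag(vcov(fit)))[fv]
      rows <- wald_rows(unname(est), unname(se), term = f, stratum = tissues)
    }
    out[[f]] <- rows
  }
  new_coeftab(do.call(rbind, c(out, list(make.row.names = FALSE))),
              n_obs = nrow(d), n_patients = n_pat)
}

#' Linear leakage gradient across the NAWM contours
#'
#' Fits the contour-restricted mixed model of leakage against contour
#' proximity to the WMH edge, with a patient random intercept and the
#' adjustment set (age, Fazekas score, blood pressure, stroke subtype,
#' smoking). Sign convention: the reported gradient is the change per
#' one-contour step *toward* the WMH, so a positive estimate means leakage
#' is higher nearer the WMH edge.
#'
#' @param table long slope table including `contour_k` tissue rows.
#' @param adjust adjustment covariates (names as in [fit_leakage_model()],
#'   plus `age`/`fazekas`/`subtype`).
#' @return a `bbb_coeftab` with the `contour_proximity` term.
#' @export
fit_contour_gradient <- function(table,
                                 adjust = c("age", "fazekas", "map",
                                            "subtype", "smoker")) {
  d <- prep_model_data(table)
  d <- d[grepl("^contour_", d$tissue), ]
  ks <- as.integer(sub("^contour_", "", d$tissue))
  present <- sort(unique(ks))
  if (length(present) < 3L)
    stop("need >= 3 contour levels; present: ",
         if (length(present)) paste(present, collapse = ", ") else "none")
  n_max <- max(present)
  d$proximity <- n_max + 1L - ks
  adj <- unname(adjust_var[adjust])
  vars <- c("slope", "proximity", adj)
  d <- d[complete.cases(d[, vars]), ]
  if (length(unique(d$patient)) < 2L) stop("at least 2 patients are required")
  X <- model.matrix(as.formula(paste("~", paste(c("proximity", adj),
                                                collapse = " + "))), d)
  assert_full_rank(X)
  form <- as.formula(paste("slope ~ proximity +", paste(adj, collapse = " + "),
                           "+ (1 | patient)"))
  w <- lmer_wald(form, d, "^proximity$")
  new_coeftab(wald_rows(unname(w$est), unname(w$se),
                        term = "contour_proximity", stratum = "nawm_contours"),
              n_obs = nrow(d), n_patients = length(unique(d$patient)))
}

#' Age-adjusted contour profiles by WMH-burden group
#'
#' Groups patients by Fazekas score (default low 0-2, medium 3-4, high
#' 5-6) and computes age-adjusted group means of each metric (leakage
#' slope, MD, FA, T1) per contour / WMH stratum: a linear model
#' `value ~ group + centred age` per stratum, evaluated at the cohort mean
#' age. Empty groups are omitted with a warning. An `ordering` attribute
#' reports, per metric and group, whether the profile is monotone toward
#' the lesion (non-decreasing for leakage/MD/T1, non-increasing for FA).
#'
#' @param table long table with `patient`, `tissue`, `age`, `fazekas` and
#'   metric columns.
#' @param metrics metric columns to profile (present ones are used).
#' @param groups named list of Fazekas scores per group; must cover 0-6.
#' @return data.frame of class `bbb_profile`: `stratum`, `metric`,
#'   `group`, `adj_mean`, `se`, `ci95_low`, `ci95_high`, `n`.
#' @export
profile_by_fazekas_group <- function(table,
                                     metrics = c("slope", "md", "fa", "t10_ms"),
                                     groups = list(low = 0:2, medium = 3:4,
                                                   high = 5:6)) {
  if (!setequal(unlist(groups), 0:6))
    stop("groups must cover Fazekas scores 0-6 exactly")
  d <- prep_model_data(table)
  metrics <- intersect(metrics, names(d))
  if (!length(metrics)) stop("no metric columns found")
  gl <- rep(names(groups), lengths(groups))
  names(gl) <- as.character(unlist(groups))
  d$faz_group <- factor(gl[as.character(d$fazekas)], levels = names(groups))
  have <- names(groups)[names(groups) %in% unique(d$faz_group)]
  if (length(have) < length(groups))
    warning("empty Fazekas group(s) omitted: ",
            paste(setdiff(names(groups), have), collapse = ", "))
  d$faz_group <- factor(as.character(d$faz_group), levels = have)
  # strata ordered away from the lesion -> toward and into the WMH
  strat_levels <- c(paste0("contour_", 10:1), "wmh_less", "wmh_intense")
  strata <- intersect(strat_levels, unique(d$tissue))
  d$age_c <- d$age - mean(d$age[!duplicated(d$patient)])
  rows <- list()
  for (st in strata) for (m in metrics) {
    ds <- d[d$tissue == st & !is.na(d[[m]]), ]
    if (!nrow(ds)) next
    ds$y <- ds[[m]]
    fit <- if (length(unique(ds$faz_group)) > 1L)
      lm(y ~ faz_group + age_c, data = ds) else lm(y ~ age_c, data = ds)
    nd <- data.frame(faz_group = factor(levels(droplevels(ds$faz_group)),
                                        levels = levels(droplevels(ds$faz_group))),
                     age_c = 0)
    pr <- predict(fit, newdata = nd, se.fit = TRUE)
    rows[[paste(st, m)]] <- data.frame(
      stratum = st, metric = m, group = as.character(nd$faz_group),
      adj_mean = unname(pr$fit), se = unname(pr$se.fit),
      ci95_low = unname(pr$fit - qnorm(0.975) * pr$se.fit),
      ci95_high = unname(pr$fit + qnorm(0.975) * pr$se.fit),
      n = vapply(as.character(nd$faz_group),
                 function(g) sum(ds$faz_group == g, na.rm = TRUE), numeric(1)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  # monotone-toward-lesion diagnostics per metric x group
  ordering <- list()
  for (m in intersect(metrics, unique(out$metric))) {
    for (g in have) {
      v <- out$adj_mean[out$metric == m & out$group == g]
      v <- v[order(match(out$stratum[out$metric == m & out$group == g],
                         strat_levels))]
      mono <- if (m == "fa") all(diff(v) <= 1e-12) else all(diff(v) >= -1e-12)
      ordering[[paste(m, g, sep = ".")]] <- mono
    }
  }
  structure(out, ordering = unlist(ordering),
            class = c("bbb_profile", "data.frame"))
}

#' Cognitive outcome model: 1-year ACE-R on WMH leakage
#'
#' Linear model of the 1-year cognitive score on standardized WMH leakage,
#' premorbid intelligence (NART), WMH burden, age and hypertension, with
#' the leakage effect optionally split by stroke subtype (lacunar vs
#' cortical interaction) and, with `include_baseline = TRUE`, baseline
#' ACE-R added so the leakage coefficient describes 1-year *change* in
#' cognition.
#'
#' @param table one row per patient (or a long slope table, from which the
#'   `wmh` rows are taken) with `acer_1yr`, `acer_baseline`, `nart`,
#'   `fazekas`, `age`, `hypertension`, `subtype` and the WMH `slope`.
#' @param include_baseline adjust for baseline ACE-R (the change model).
#' @param by_subtype estimate separate leakage effects for lacunar and
#'   cortical patients.
#' @param min_patients minimum patients with a 1-year score (default 20).
#' @return a `bbb_coeftab`; leakage rows are per SD of WMH leakage.
#' @export
fit_cognition_model <- function(table, include_baseline = TRUE,
                                by_subtype = FALSE, min_patients = 20L) {
  d <- prep_model_data(table)
  if ("tissue" %in% names(d)) d <- d[d$tissue == "wmh", ]
  if (!nrow(d) || is.null(d$acer_1yr)) stop("no cognition data available")
  vars <- c("acer_1yr", "slope", "nart", "fazekas", "age5", "hypertension",
            "lacunar", if (include_baseline) "acer_baseline")
  d <- d[complete.cases(d[, vars]), ]
  if (nrow(d) < min_patients)
    stop(sprintf("only %d patients with 1-year ACE-R (< %d required)",
                 nrow(d), min_patients))
  d$leak_z <- as.numeric(scale(d$slope))
  base_terms <- c("nart", "fazekas", "age5", "hypertension",
                  if (include_baseline) "acer_baseline")
  leak_terms <- if (by_subtype) "leak_z:lacunar + leak_z:cortical" else "leak_z"
  if (by_subtype) d$cortical <- 1 - d$lacunar
  rhs <- paste(c(leak_terms, base_terms), collapse = " + ")
  X <- model.matrix(as.formula(paste("~", rhs)), d)
  assert_full_rank(X)
  fit <- lm(as.formula(paste("acer_1yr ~", rhs)), data = d)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  keep <- grep("leak_z|nart|fazekas|age5|hypertension|acer_baseline",
               names(est), value = TRUE)
  tab <- wald_rows(unname(est[keep]), unname(se[keep]), term = keep,
                   stratum = "wmh")
  new_coeftab(tab, n_obs = nrow(d), n_patients = nrow(d))
}

#' Longitudinal (direct) leakage model on enhancement time courses
#'
#' The one-stage alternative to slope-then-model: enhancement is regressed
#' on time with covariate-by-time interactions and a random per-patient
#' time slope, within each tissue stratum. The time-by-covariate
#' coefficient estimates the covariate's effect on the enhancement slope
#' and should agree in sign and approximate magnitude with the two-stage
#' route on the same data.
#'
#' @param enh_table long data.frame with `patient`, `tissue`, `time_min`,
#'   `enhancement` and covariate columns.
#' @param focus one of `"age"`, `"fazekas"`, `"subtype"`.
#' @param adjust additional covariates interacted with time.
#' @return a `bbb_coeftab` with one row per tissue: effect of `focus` on
#'   the enhancement slope (per minute per covariate unit).
#' @export
fit_leakage_longitudinal <- function(enh_table, focus = "fazekas",
                                     adjust = c("age", "subtype")) {
  focus <- match.arg(focus, c("age", "fazekas", "subtype"))
  d <- prep_model_data(enh_table)
  fv <- focus_var[[focus]]
  adj <- unname(adjust_var[adjust])
  rows <- list()
  for (tis in unique(d$tissue)) {
    ds <- d[d$tissue == tis, ]
    inter <- paste0("time_min:", c(fv, adj))
    form <- as.formula(paste("enhancement ~ 0 + time_min +",
                             paste(inter, collapse = " + "),
                             "+ (0 + time_min | patient)"))
    fit <- suppressMessages(lmer(form, data = ds, REML = TRUE,
                                 control = lmerControl(calc.derivs = FALSE,
                                                       check.nobs.vs.nlev = "ignore",
                                                       check.nobs.vs.nRE = "ignore")))
    fe <- fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    nm <- grep(paste0("time_min:", fv, "$"), names(fe), value = TRUE)
    rows[[tis]] <- wald_rows(unname(fe[nm]), unname(se[nm]),
                             term = focus, stratum = tis)
  }
  new_coeftab(do.call(rbind, c(rows, list(make.row.names = FALSE))),
              n_obs = nrow(d), n_patients = length(unique(d$patient)))
}
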