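#' Default 30-metabolite panel
#'
#' Ten lipid-metabolism metabolites, ten amino acids (incl. derivatives),
#' ten others, with plasma-scale mean concentrations (uM), per-metabolite
#' coefficients of variation, and bone-marrow-minus-blood mean shifts at
#' day 0 (diagnosis, marrow full of blasts) and day 29 (remission). Means
#' and shifts for lactate, urea, glutamate, triacylglyceride, glycine,
#' glucose, cholesterol esters, glutamine and 3-hydroxybutyrate follow the
#' published compartment means for pediatric ALL; the remaining entries are
#' realistic plasma values. The day-0 shifts encode the cancer-state
#' pattern: glutamate, lactate, choline and hypoxanthine elevated in
#' marrow; glucose, glutamine, ketone bodies and free fatty acids depleted.
#'
#' @return Data frame with columns `metabolite`, `class`, `mean_um`, `cv`,
#'   `shift_day0`, `shift_day29`.
#' @export
default_panel <- function() {
  p <- rbind(
    # lipid metabolism
    c("choline",                  "lipid_metabolism", 22,      0.25,   8,     2),
    c("glycero-3-phosphocholine", "lipid_metabolism", 18,      0.30,   6,     3),
    c("acetylcarnitine",          "lipid_metabolism", 8,       0.30,   2,     0),
    c("glycerol",                 "lipid_metabolism", 120,     0.35,  -35,    12),
    c("free cholesterol",         "lipid_metabolism", 1150,    0.25,  -60,    10),
    c("cholesterol esters",       "lipid_metabolism", 3545.79, 0.25,  -192.99, 35.54),
    c("triacylglyceride",         "lipid_metabolism", 2051.74, 0.30,   247.33, -39.34),
    c("myristic acid",            "lipid_metabolism", 55,      0.40,  -12,    -2),
    c("palmitic acid",            "lipid_metabolism", 1400,    0.35,  -160,   -20),
    c("palmitoleic acid",         "lipid_metabolism", 32,      0.40,  -9,     -1),
    # amino acids, derivatives, analogues
    c("glutamate",                "amino_acid",       156.271, 0.35,   303.71, -25.64),
    c("glutamine",                "amino_acid",       442.421, 0.20,  -89.64,  7.59),
    c("glycine",                  "amino_acid",       354.293, 0.25,   95.78,  16.82),
    c("alanine",                  "amino_acid",       350,     0.25,   55,     10),
    c("valine",                   "amino_acid",       225,     0.20,   30,     5),
    c("aspartate",                "amino_acid",       18,      0.35,   14,     2),
    c("asparagine",               "amino_acid",       48,      0.30,  -6,      0),
    c("methionine",               "amino_acid",       26,      0.25,   7,      1),
    c("pyroglutamate",            "amino_acid",       45,      0.30,  -14,    -2),
    c("creatine",                 "amino_acid",       60,      0.30,   8,      2),
    # other
    c("lactate",                  "other",            2378.42, 0.30,   1040.27, -418.96),
    c("glucose",                  "other",            6066.73, 0.20,  -691.57, -627.42),
    c("urea",                     "other",            4464.38, 0.30,   553.85, -642.82),
    c("3-hydroxybutyrate",        "other",            236.31,  0.45,  -89.15, -20.74),
    c("acetoacetate",             "other",            62,      0.45,  -24,    -6),
    c("acetone",                  "other",            30,      0.40,  -11,    -3),
    c("hypoxanthine",             "other",            9,       0.35,   7,      2),
    c("uridine",                  "other",            14,      0.30,   5,      1),
    c("formate",                  "other",            40,      0.30,   6,      2),
    c("pyruvate",                 "other",            68,      0.35,   14,    -4)
  )
  data.frame(metabolite = p[, 1], class = p[, 2],
             mean_um = as.numeric(p[, 3]), cv = as.numeric(p[, 4]),
             shift_day0 = as.numeric(p[, 5]), shift_day29 = as.numeric(p[, 6]),
             stringsAsFactors = FALSE)
}

#' Specify a correlated metabolite block
#'
#' Members share one latent Gaussian factor on the log scale so that their
#' pairwise correlation in the configured space (`BM`, `PB` or the
#' per-patient `BM_minus_PB` differences) at `active_day` is approximately
#' `target_correlation`.
#'
#' @param members Character vector (>= 2) of panel metabolite names.
#' @param target_correlation Target pairwise correlation in (-1, 1).
#' @param active_day Day at which the block is active (0, 8 or 29).
#' @param active_space `"BM"`, `"PB"` or `"BM_minus_PB"`.
#' @return A `block_spec` list.
#' @export
block_spec <- function(members, target_correlation, active_day,
                       active_space = c("BM_minus_PB", "BM", "PB")) {
  active_space <- match.arg(active_space)
  members <- normalize_metabolite_name(members)
  if (length(members) < 2) stop("a block needs at least 2 members")
  if (!is.numeric(target_correlation) || target_correlation <= -1 ||
      target_correlation >= 1) {
    stop("`target_correlation` must lie in (-1, 1)")
  }
  if (!active_day %in% DAYS) stop("`active_day` must be one of ",
                                  paste(DAYS, collapse = ", "))
  if (target_correlation < 0 && length(members) > 2) {
    stop("mutually negative equicorrelation is infeasible for > 2 members")
  }
  structure(list(members = members, target_correlation = target_correlation,
                 active_day = as.integer(active_day),
                 active_space = active_space),
            class = "block_spec")
}

#' Default planted blocks: the study's network-level signature
#'
#' A lipid-metabolism block correlated (r ~ 0.9) in the day-0 marrow-minus-
#' blood differences (the cancer state) and an amino-acid block correlated
#' at day 29 (remission) -- the structure the relevance-network/enrichment
#' stage is designed to detect.
#'
#' @param panel Panel data frame, by default [default_panel()].
#' @param target_correlation Pairwise target correlation, default 0.9.
#' @return List of two [block_spec()]s.
#' @export
default_blocks <- function(panel = default_panel(), target_correlation = 0.9) {
  list(
    block_spec(panel$metabolite[panel$class == "lipid_metabolism"],
               target_correlation, active_day = 0, active_space = "BM_minus_PB"),
    block_spec(panel$metabolite[panel$class == "amino_acid"],
               target_correlation, active_day = 29, active_space = "BM_minus_PB")
  )
}

#' Configure a synthetic paired cohort
#'
#' Defaults reproduce the study conditions: 10 patients, paired marrow/
#' blood samples (marrow at days 0 and 29; blood at days 0, 8 and 29), the
#' 30-metabolite panel of [default_panel()] at published concentration
#' scales, the two planted blocks of [default_blocks()], and 5% missing
#' cells.
#'
#' @param n_patients Number of patients (>= 3), default 10.
#' @param panel Panel data frame (see [default_panel()] for the columns).
#' @param blocks List of [block_spec()]s; may be empty.
#' @param missing_rate Fraction of cells set missing, in `[0, 1)`.
#' @param within_patient_cor Share of per-metabolite log-scale variance
#'   from a patient-day random effect common to both compartments (the
#'   marrow/blood within-patient covariance, unreported in the study and
#'   therefore exposed as a parameter), default 0.3.
#' @param seed Integer RNG seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 10, panel = default_panel(),
                          blocks = default_blocks(panel),
                          missing_rate = 0.05, within_patient_cor = 0.3,
                          seed = 1L) {
  if (n_patients < 3) stop("`n_patients` must be >= 3")
  need <- c("metabolite", "class", "mean_um", "cv", "shift_day0", "shift_day29")
  if (!all(need %in% names(panel))) {
    stop("panel must have columns: ", paste(need, collapse = ", "))
  }
  panel$metabolite <- normalize_metabolite_name(panel$metabolite)
  if (any(panel$mean_um <= 0)) stop("panel means must be > 0")
  if (any(panel$mean_um + panel$shift_day0 <= 0) ||
      any(panel$mean_um + panel$shift_day29 <= 0)) {
    stop("mean + shift must stay > 0 for every metabolite")
  }
  bad_cls <- setdiff(unique(panel$class), METABOLITE_CLASSES)
  if (length(bad_cls)) stop("unknown panel class(es): ",
                            paste(bad_cls, collapse = ", "))
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must be in [0, 1)")
  }
  if (within_patient_cor < 0 || within_patient_cor >= 1) {
    stop("`within_patient_cor` must be in [0, 1)")
  }
  all_members <- unlist(lapply(blocks, `[[`, "members"))
  absent <- setdiff(all_members, panel$metabolite)
  if (length(absent)) {
    stop("block member(s) not in panel: ", paste(absent, collapse = ", "))
  }
  if (anyDuplicated(all_members)) {
    stop("block memberships must not overlap")
  }
  structure(list(n_patients = as.integer(n_patients), panel = panel,
                 blocks = blocks, missing_rate = missing_rate,
                 within_patient_cor = within_patient_cor,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Annotation map implied by a cohort config's panel
#' @param config A `cohort_config` (or a panel data frame).
#' @return Named character vector as from [annotation_map()].
#' @export
cohort_annotation <- function(config) {
  panel <- if (inherits(config, "cohort_config")) config$panel else config
  annotation_map(panel$metabolite, panel$class)
}

# Block factor loading that yields pairwise correlation r among member
# observations in the configured space, given patient-effect share w.
# Single-compartment spaces: y_c = a f + sqrt(w) z + sqrt(1-a^2-w) e,
# corr = a^2 = r. Difference space: y_BM - y_PB with loadings +/-a:
# corr = 4a^2 / (4a^2 + 2(1 - a^2 - w)) = r  =>  a^2 = r(1-w)/(2-r).
block_loading <- function(r, space, w) {
  a2 <- if (space == "BM_minus_PB") abs(r) * (1 - w) / (2 - abs(r)) else abs(r)
  if (a2 + w > 1) stop("block correlation and within_patient_cor incompatible")
  sqrt(a2)
}

#' Generate a synthetic paired cohort
#'
#' Concentrations are log-normal at the configured means and coefficients
#' of variation. On the standardized log scale each observation is a sum of
#' a block factor (per patient, planted only in the configured space and
#' day), a patient-day effect shared by the two compartments, and
#' idiosyncratic noise, with variance shares chosen so that block members'
#' pairwise correlation in the active space approximates the target.
#' Compartment mean shifts are realized by shifting the marrow mean at the
#' corresponding day. Fully reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A `conc_table` with marrow samples at days 0 and 29 and blood
#'   samples at days 0, 8 and 29 for every patient.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  panel <- config$panel
  n <- config$n_patients
  p <- nrow(panel)
  w <- config$within_patient_cor
  patients <- sprintf("P%02d", seq_len(n))
  design <- rbind(
    expand.grid(patient_id = patients, compartment = "BM", day = c(0L, 29L),
                stringsAsFactors = FALSE),
    expand.grid(patient_id = patients, compartment = "PB", day = c(0L, 8L, 29L),
                stringsAsFactors = FALSE))
  ns <- nrow(design)
  day_idx <- match(design$day, DAYS)

  nb <- length(config$blocks)
  f <- if (nb) matrix(stats::rnorm(nb * n), nb, n) else NULL
  z <- array(stats::rnorm(n * length(DAYS) * p), c(n, length(DAYS), p))
  eps <- matrix(stats::rnorm(ns * p), ns, p)

  # per-sample, per-metabolite block loading
  b <- matrix(0, ns, p)
  fac <- matrix(0, ns, p)          # block factor value broadcast to samples
  pat_i <- match(design$patient_id, patients)
  if (nb) {
    for (k in seq_len(nb)) {
      blk <- config$blocks[[k]]
      j <- match(blk$members, panel$metabolite)
      a <- block_loading(blk$target_correlation, blk$active_space, w)
      s <- sign(blk$target_correlation)
      rows <- which(design$day == blk$active_day &
                      (blk$active_space == "BM_minus_PB" |
                         design$compartment == blk$active_space))
      for (jj in seq_along(j)) {
        load <- a * if (s < 0 && jj %% 2 == 0) -1 else 1
        for (rr in rows) {
          bb <- load
          if (blk$active_space == "BM_minus_PB" &&
              design$compartment[rr] == "PB") bb <- -bb
          b[rr, j[jj]] <- bb
          fac[rr, j[jj]] <- f[k, pat_i[rr]]
        }
      }
    }
  }
  zmat <- matrix(0, ns, p)
  for (jj in seq_len(p)) zmat[, jj] <- z[cbind(pat_i, day_idx, jj)]
  y <- b * fac + sqrt(w) * zmat + sqrt(pmax(1 - b^2 - w, 0)) * eps

  sigma <- sqrt(log(1 + panel$cv^2))
  x <- matrix(NA_real_, ns, p)
  for (jj in seq_len(p)) {
    mean_c <- rep(panel$mean_um[jj], ns)
    is_bm <- design$compartment == "BM"
    mean_c[is_bm & design$day == 0L] <- panel$mean_um[jj] + panel$shift_day0[jj]
    mean_c[is_bm & design$day == 29L] <- panel$mean_um[jj] + panel$shift_day29[jj]
    mu <- log(mean_c) - sigma[jj]^2 / 2
    x[, jj] <- exp(mu + sigma[jj] * y[, jj])
  }
  colnames(x) <- panel$metabolite
  tab <- as_concentration_table(cbind(design, as.data.frame(x, check.names = FALSE)))
  if (config$missing_rate > 0) {
    tab <- inject_missing(tab, config$missing_rate, seed = NULL)
  }
  tab
}

#' Set concentration cells missing completely at random
#'
#' @param table A `conc_table`.
#' @param rate Per-cell missingness probability in `[0, 1)`.
#' @param seed Integer seed, or `NULL` to draw from the current RNG state
#'   (used when called inside an already-seeded generator).
#' @return The table with cells set to `NA`.
#' @export
inject_missing <- function(table, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("`rate` must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(table)
  mets <- ct_metabolites(table)
  mask <- matrix(stats::runif(nrow(table) * length(mets)) < rate,
                 nrow(table), length(mets))
  for (j in seq_along(mets)) {
    table[[mets[j]]][mask[, j]] <- NA_real_
  }
  table
}

#' Generate a paired two-class feature matrix (spectra-like proxy)
#'
#' Emulates binned spectra from a paired design: two samples per subject
#' (one per class), log-normal intensities around a common base spectrum,
#' a subject random effect, and a class-difference direction whose
#' magnitude is `class_effect` (log-scale units; 0 gives exchangeable
#' pairs). An optional per-sample dilution factor can be added for testing
#' probabilistic quotient normalization.
#'
#' @param n_subjects Number of subjects.
#' @param n_features Number of features (>= 2).
#' @param class_effect Within-subject class separation on the log scale.
#' @param seed Integer seed.
#' @param between_sd Subject random-effect SD (log scale), default 1.
#' @param noise_sd Residual SD (log scale), default 0.3.
#' @param dilution_sd Log-SD of per-sample dilution factors, default 0.
#' @return List with `x` (2*n_subjects x n_features intensity matrix),
#'   `subject`, `class` (factors `"A"`/`"B"`), `dilution`.
#' @export
generate_feature_matrix <- function(n_subjects, n_features, class_effect,
                                    seed = 1L, between_sd = 1, noise_sd = 0.3,
                                    dilution_sd = 0) {
  if (n_features < 2) stop("`n_features` must be >= 2")
  set.seed(seed)
  base <- stats::rnorm(n_features, 0, 0.5)
  v <- stats::rnorm(n_features)
  v <- v / sqrt(sum(v^2))
  subj <- matrix(stats::rnorm(n_subjects * n_features, 0, between_sd),
                 n_subjects, n_features)
  n_samp <- 2 * n_subjects
  noise <- matrix(stats::rnorm(n_samp * n_features, 0, noise_sd),
                  n_samp, n_features)
  subject <- rep(seq_len(n_subjects), each = 2)
  cls <- rep(c("A", "B"), n_subjects)
  side <- ifelse(cls == "A", 0.5, -0.5)
  logx <- matrix(base, n_samp, n_features, byrow = TRUE) +
    subj[subject, , drop = FALSE] +
    outer(side * class_effect, v) + noise
  dilution <- exp(stats::rnorm(n_samp, 0, dilution_sd))
  x <- exp(logx) * 100 * dilution
  colnames(x) <- sprintf("f%03d", seq_len(n_features))
  rownames(x) <- sprintf("S%02d_%s", subject, cls)
  list(x = x, subject = factor(subject), class = factor(cls),
       dilution = dilution)
}
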