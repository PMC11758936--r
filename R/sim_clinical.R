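#' Simulate subject-level latent trajectories
#'
#' Draws, per subject, demographics, a lesion-load severity (independent of
#' the disability trajectory except through the explicit couplings of the
#' configuration), a latent baseline EDSS level and per-year slope, visit
#' times, and carrier indicators for the planted effects.
#'
#' @param cfg a [sim_config].
#' @return data.frame with one row per subject.
#' @export
simulate_subjects <- function(cfg) {
  n_p <- cfg$n_patients
  n_c <- cfg$n_controls
  with_seed(derive_seed(cfg$seed, "subjects"), {
    id <- c(sprintf("P%03d", seq_len(n_p)),
            if (n_c > 0) sprintf("HC%03d", seq_len(n_c)))
    group <- c(rep("patient", n_p), rep("control", n_c))
    sex <- ifelse(runif(n_p + n_c) <
                    ifelse(group == "patient", 0.70, 0.45), "F", "M")
    age0 <- clip(ifelse(group == "patient", rnorm(n_p + n_c, 37.2, 10.6),
                        rnorm(n_p + n_c, 42.4, 15.7)), 18, 75)
    dd <- ifelse(group == "patient",
                 pmax(0.2, rnorm(n_p + n_c, 9.1, 7.9)), NA)
    lesion_severity <- ifelse(group == "patient",
                              exp(rnorm(n_p + n_c, 0, 0.5)) - 0.3, 0)
    lesion_severity <- pmax(lesion_severity, 0)
    l0 <- ifelse(group == "patient",
                 pmax(0, rnorm(n_p + n_c, 2.5, 1.4)), NA)
    slope <- ifelse(group == "patient",
                    rnorm(n_p + n_c, cfg$edss_slope_mean, cfg$edss_slope_sd),
                    NA)
    n_visits <- ifelse(group == "patient",
                       sample(seq(cfg$visits_per_subject[1],
                                  cfg$visits_per_subject[2]),
                              n_p + n_c, replace = TRUE), 1L)
    total_fu <- ifelse(group == "patient",
                       runif(n_p + n_c, cfg$followup_years[1],
                             cfg$followup_years[2]), 0)
    pd <- cfg$planted_disconnection_component
    carrier_disc <- group == "patient" &
      (if (is.null(pd)) FALSE else runif(n_p + n_c) <= pd$carrier_fraction)
    ps <- cfg$planted_similarity_component
    carrier_sim <- group == "patient" &
      (if (is.null(ps)) FALSE else runif(n_p + n_c) <= ps$carrier_fraction)
    data.frame(subject = id, group = group, sex = sex, age0 = age0,
               disease_duration = dd, lesion_severity = lesion_severity,
               l0 = l0, slope = slope, n_visits = n_visits,
               total_followup = total_fu, carrier_disc = carrier_disc,
               carrier_sim = carrier_sim, stringsAsFactors = FALSE)
  })
}

visit_times <- function(subj_row, cfg) {
  if (subj_row$group != "patient" || subj_row$n_visits == 1)
    return(0)
  with_seed(derive_seed(cfg$seed, subj_row$subject, "visits"), {
    k <- subj_row$n_visits
    inner <- if (k > 2) sort(runif(k - 2, 0.05, 0.95)) else numeric(0)
    c(0, inner * subj_row$total_followup, subj_row$total_followup)
  })
}

#' Simulate the clinical / longitudinal cohort table
#'
#' Generates per-visit clinical records from latent severity trajectories:
#' EDSS on the 0-10 half-point grid through a monotone link (baseline level +
#' per-year slope + noise, rounded half-up and clipped), inverted SDMT
#' z-scores (higher = worse), brain and intracranial volumes with
#' patient atrophy and a per-year z-scored BPF drift, plus a long-term
#' (5-17 year) follow-up EDSS per patient from which the confirmed
#' disability progression (CDP) label is computed with [cdp_label()].  The
#' log-odds of an extra long-term progression jump increase with
#' `cdp_effect` per standard deviation of `planted_score`.
#'
#' @param subjects data.frame from [simulate_subjects()].
#' @param cfg a [sim_config].
#' @param planted_score optional numeric vector (one per subject row, NA for
#'   controls): baseline planted-component disconnection score coupling
#'   long-term CDP odds.
#' @return data.frame with one row per visit (class `cohort_table`): columns
#'   subject, group, visit, followup_time, age, sex, disease_duration, EDSS,
#'   SDMT_z (inverted), TLV (filled by the pipeline), brain_vol, icv, BPF,
#'   and for the last... see Details; long-term columns `edss_longterm`,
#'   `followup_longterm`, `CDP` are attached to baseline rows.
#' @export
make_clinical <- function(subjects, cfg, planted_score = NULL) {
  if (is.null(planted_score)) planted_score <- rep(NA_real_, nrow(subjects))
  zs <- planted_score
  ok <- is.finite(zs)
  if (sum(ok) > 1 && sd(zs[ok]) > 0) {
    zs[ok] <- (zs[ok] - mean(zs[ok])) / sd(zs[ok])
  } else zs[ok] <- 0
  rows <- vector("list", nrow(subjects))
  hc_bpf_sd <- 0.012
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    tv <- visit_times(s, cfg)
    with_seed(derive_seed(cfg$seed, s$subject, "clinical"), {
      icv <- rnorm(1, 1.5e6, 1.2e5)
      male <- as.integer(s$sex == "M")
      # normal-aging prediction at the age of each visit; disease drift is
      # added on top so the z-scored trajectory declines at bpf_slope_mean
      bpf_base_pred <- 0.85 - 0.0015 * (s$age0 + tv - 40) - 0.004 * male
      if (s$group == "patient") {
        atrophy <- pmax(0, 0.015 + 0.008 * s$lesion_severity +
                          rnorm(1, 0, 0.015))
        edss <- round_half_up_05(clip(s$l0 + s$slope * tv +
                                        rnorm(length(tv), 0, 0.25), 0, 10))
        sdmt <- 1.1 + 0.35 * (s$l0 - 2.5) + rnorm(length(tv), 0, 1)
        bpf <- bpf_base_pred - atrophy + rnorm(1, 0, 0.004) +
          cfg$bpf_slope_mean * hc_bpf_sd * tv
        # long-term follow-up and CDP; a stable-course subgroup (mostly
        # relapsing-remitting) barely progresses over the long term
        t_lt <- runif(1, 5, 17)
        stable <- runif(1) < 0.45
        p_jump <- plogis(-2.0 + cfg$cdp_effect * ifelse(is.finite(zs[i]),
                                                        zs[i], 0))
        jump <- 1.5 * rbinom(1, 1, p_jump)
        drift <- if (stable) 0.1 * s$slope else s$slope
        edss_lt <- round_half_up_05(clip(s$l0 + drift * t_lt + jump +
                                           rnorm(1, 0, 0.6), 0, 10))
        cdp <- cdp_label(edss[1], edss_lt)
      } else {
        edss <- rep(NA_real_, length(tv))
        sdmt <- -rnorm(length(tv), 0, 1) # inverted HC z-scores
        bpf <- bpf_base_pred + rnorm(1, 0, hc_bpf_sd)
        t_lt <- NA_real_; edss_lt <- NA_real_; cdp <- NA
      }
      rows[[i]] <- data.frame(
        subject = s$subject, group = s$group, visit = seq_along(tv),
        followup_time = tv, age = s$age0 + tv, sex = s$sex,
        disease_duration = s$disease_duration + tv,
        EDSS = edss, SDMT_z = sdmt, TLV = NA_real_,
        brain_vol = bpf * icv, icv = icv, BPF = bpf,
        edss_longterm = ifelse(seq_along(tv) == 1, edss_lt, NA),
        followup_longterm = ifelse(seq_along(tv) == 1, t_lt, NA),
        CDP = ifelse(seq_along(tv) == 1, cdp, NA),
        stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_table", "data.frame")
  out
}
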