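#' Simulate a complete synthetic cohort
#'
#' Runs the full generator: parcellation, streamline atlas, per-visit lesion
#' masks and disconnection matrices for patients, vertex features and
#' morphometric similarity matrices (optional), and the clinical table with
#' long-term confirmed-disability-progression labels.  The baseline
#' planted-component disconnection score couples CDP odds through
#' `cfg$cdp_effect`.
#'
#' @param cfg a [sim_config].
#' @param compute_mind compute similarity matrices (the expensive stage;
#'   default TRUE).
#' @param mind_visits `"baseline"` (default) or `"all"`.
#' @param keep_masks retain the per-visit lesion masks in the result.
#' @return object of class `sim_cohort`: `cfg`, `parcellation`, `atlas`,
#'   `subjects`, `cohort`, `disconnection` (named list, patients x visits),
#'   `mind` (named list or NULL), `masks` (optional).
#' @export
simulate_cohort <- function(cfg, compute_mind = TRUE,
                            mind_visits = c("baseline", "all"),
                            keep_masks = FALSE) {
  mind_visits <- match.arg(mind_visits)
  parc <- make_parcellation(cfg)
  atlas <- make_streamline_atlas(parc, cfg)
  subjects <- simulate_subjects(cfg)
  nt <- parc$node_table

  disc <- list()
  masks <- list()
  tlv <- list()
  pd0 <- cfg$planted_disconnection_component
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    if (s$group != "patient") next
    tv <- visit_times(s, cfg)
    # planted progressive disconnection is tied to the subject's latent
    # disability slope, so faster EDSS worsening means faster accrual
    pm <- if (!is.null(pd0) && pd0$progression > 0)
      max(0, s$slope) / max(cfg$edss_slope_mean, 1e-8) else 1
    for (v in seq_along(tv)) {
      m <- make_lesions(s$lesion_severity, parc, cfg,
                        subject_id = s$subject, followup_time = tv[v],
                        carrier = s$carrier_disc, atlas = atlas,
                        prog_multiplier = pm)
      key <- sprintf("%s_v%d", s$subject, v)
      disc[[key]] <- disconnection_matrix(m, atlas, nt)
      tlv[[key]] <- total_lesion_volume(m)
      if (keep_masks) masks[[key]] <- m
    }
  }

  pd <- cfg$planted_disconnection_component
  planted_score <- rep(NA_real_, nrow(subjects))
  if (!is.null(pd)) {
    for (i in seq_len(nrow(subjects))) {
      key <- sprintf("%s_v1", subjects$subject[i])
      if (!is.null(disc[[key]]))
        planted_score[i] <- mean(disc[[key]]$values[pd$edges])
    }
  }

  cohort <- make_clinical(subjects, cfg, planted_score)
  keys <- sprintf("%s_v%d", cohort$subject, cohort$visit)
  cohort$TLV <- ifelse(cohort$group == "patient",
                       unlist(tlv)[keys], 0)
  cohort$planted_score <- planted_score[match(cohort$subject,
                                              subjects$subject)]

  mind <- NULL
  if (compute_mind) {
    mind <- list()
    for (i in seq_len(nrow(subjects))) {
      s <- subjects[i, ]
      tv <- if (s$group == "patient") visit_times(s, cfg) else 0
      vs <- if (mind_visits == "baseline") 1L else seq_along(tv)
      for (v in vs) {
        vf <- make_vertex_features(parc, cfg, subject_id = s$subject,
                                   group = s$group,
                                   carrier = isTRUE(s$carrier_sim),
                                   followup_time = tv[v])
        mind[[sprintf("%s_v%d", s$subject, v)]] <-
          mind_matrix(vf, node_table = nt)
      }
    }
  }

  structure(list(cfg = cfg, parcellation = parc, atlas = atlas,
                 subjects = subjects, cohort = cohort, disconnection = disc,
                 mind = mind, masks = if (keep_masks) masks else NULL),
            class = "sim_cohort")
}

#' Stack connectivity matrices into an observation-by-edge matrix
#'
#' @param ms list of [conn_matrix] objects sharing node set and mask.
#' @param edge_mask optional mask overriding the first matrix's own.
#' @return list with `Y` (length(ms) x edges), `pairs`, `n_nodes`, `ev`.
#' @export
stack_conn_matrices <- function(ms, edge_mask = NULL) {
  ev <- vectorize_edges(ms[[1]], edge_mask)
  Y <- t(vapply(ms, function(m) m$values[ev$mask], numeric(sum(ev$mask))))
  list(Y = Y, pairs = ev$pairs, n_nodes = ev$n_nodes, ev = ev)
}

#' Run the whole analysis pipeline from one configuration
#'
#' One-call (and one-config) entry point: simulates the cohort, writes every
#' declared output (parcellation and probability maps as NIfTI, atlas as
#' JSON-lines, node/cohort tables and matrices as TSV) and runs the analysis
#' stack — baseline similarity group NBS, baseline EDSS-disconnection NBS,
#' longitudinal disconnection NBS, scalar mixed models for EDSS / log(1+TLV)
#' / BPF z, subnetwork z-score summaries with annualized-change Spearman and
#' partial correlations, multi-scale coupling, and (optionally) long-term
#' CDP prediction — collecting every statistic into `report.json`.
#' Fully deterministic given `seed`.
#'
#' @param config list (or path to a YAML file) with optional blocks `sim`
#'   (overrides for [sim_config()]) and `analysis` (`n_perm`, `p_primary`,
#'   `do_predict`, `predict_budget`, `predict_repeats`, `predict_n_perm`).
#' @param out_dir output directory (created).
#' @param seed master seed; overrides the config seed.
#' @return the report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  simcfg <- config$sim %||% list()
  simcfg$seed <- as.integer(seed)
  cfg <- do.call(sim_config, simcfg)
  an <- config$analysis %||% list()
  n_perm <- an$n_perm %||% 500
  p_primary <- an$p_primary %||% 0.01
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, "matrices"), recursive = TRUE)
  dir.create(file.path(out_dir, "matrices"), showWarnings = FALSE)

  co <- simulate_cohort(cfg, compute_mind = TRUE, mind_visits = "all",
                        keep_masks = TRUE)
  parc <- co$parcellation
  nt <- parc$node_table

  # ---- declared outputs -------------------------------------------------
  write_volume_nifti(parc$labels, file.path(out_dir, "parcellation.nii.gz"),
                     parc$voxel_size)
  write_tsv(nt, file.path(out_dir, "node_table.tsv"))
  write_streamline_atlas(co$atlas, file.path(out_dir, "atlas.jsonl"))
  write_tsv(co$cohort, file.path(out_dir, "cohort.tsv"))
  base_keys <- sprintf("%s_v1", co$subjects$subject[co$subjects$group == "patient"])
  base_masks <- co$masks[base_keys]
  write_volume_nifti(lesion_probability_map(base_masks),
                     file.path(out_dir, "lesion_probability.nii.gz"),
                     parc$voxel_size)
  write_volume_nifti(disconnection_probability_map(base_masks, co$atlas),
                     file.path(out_dir, "disconnection_probability.nii.gz"),
                     parc$voxel_size)
  for (k in names(co$disconnection))
    write_conn_matrix(co$disconnection[[k]],
                      file.path(out_dir, "matrices", paste0("disc_", k, ".tsv")))
  for (k in names(co$mind))
    write_conn_matrix(co$mind[[k]],
                      file.path(out_dir, "matrices", paste0("mind_", k, ".tsv")))

  report <- list(seed = seed, n_patients = cfg$n_patients,
                 n_controls = cfg$n_controls, n_perm = n_perm,
                 p_primary = p_primary)
  ch <- co$cohort
  base <- ch[ch$visit == 1, ]
  hc <- base[base$group == "control", ]
  pw <- base[base$group == "patient", ]

  # BPF z against the healthy-control reference
  ch$BPF_z <- bpf_z(ch$brain_vol, ch$icv, ch$age, ch$sex,
                    data.frame(brain_vol = hc$brain_vol, icv = hc$icv,
                               age = hc$age, sex = hc$sex))
  base$BPF_z <- ch$BPF_z[ch$visit == 1]
  report$mean_bpf_z_patients <- mean(base$BPF_z[base$group == "patient"])
  report$cdp_rate <- mean(pw$CDP, na.rm = TRUE)

  # ---- baseline group NBS on similarity ---------------------------------
  mind_base <- co$mind[sprintf("%s_v1", base$subject)]
  st <- stack_conn_matrices(mind_base)
  des <- make_design(transform(base, grp = as.integer(group == "patient"),
                               age2 = age^2, sexM = as.integer(sex == "M")),
                     "grp", c("age", "age2", "sexM"))
  nbs_grp <- nbs_glm(st$Y, des, p_primary, n_perm, seed = derive_seed(seed, "g"),
                     pairs = st$pairs, n_nodes = st$n_nodes)
  report$similarity_group_nbs <- nbs_summary(nbs_grp)

  # ---- baseline EDSS ~ disconnection NBS (TLV-adjusted) -----------------
  pwb <- transform(pw, age2 = age^2, sexM = as.integer(sex == "M"),
                   logTLV = log1p_tlv(TLV))
  disc_base <- co$disconnection[sprintf("%s_v1", pwb$subject)]
  std <- stack_conn_matrices(disc_base)
  des_e <- make_design(pwb, "EDSS", c("age", "age2", "sexM", "logTLV"))
  nbs_edss <- nbs_glm(std$Y, des_e, p_primary, n_perm,
                      seed = derive_seed(seed, "e"),
                      pairs = std$pairs, n_nodes = std$n_nodes)
  report$edss_disconnection_nbs <- nbs_summary(nbs_edss)

  # ---- longitudinal disconnection NBS -----------------------------------
  chp <- ch[ch$group == "patient", ]
  keys <- sprintf("%s_v%d", chp$subject, chp$visit)
  stl <- stack_conn_matrices(co$disconnection[keys])
  base_age <- pwb$age[match(chp$subject, pwb$subject)]
  nuis <- cbind(age = base_age, age2 = base_age^2,
                sexM = as.integer(chp$sex == "M"))
  nbs_long <- nbs_lmm(stl$Y, chp$followup_time, chp$subject, nuis,
                      p_primary, n_perm, seed = derive_seed(seed, "l"),
                      pairs = stl$pairs, n_nodes = stl$n_nodes)
  report$longitudinal_disconnection_nbs <- nbs_summary(nbs_long)

  # ---- scalar mixed models ----------------------------------------------
  sl_edss <- fit_scalar_lmm(chp$EDSS, chp$followup_time, chp$subject)
  sl_tlv <- fit_scalar_lmm(log1p_tlv(chp$TLV), chp$followup_time, chp$subject)
  sl_bpf <- fit_scalar_lmm(chp$BPF_z, chp$followup_time, chp$subject)
  report$edss_slope <- unname(sl_edss$B["time"])
  report$edss_slope_se <- unname(sl_edss$se["time"])
  report$logtlv_slope <- unname(sl_tlv$B["time"])
  report$bpfz_slope <- unname(sl_bpf$B["time"])

  # ---- subnetwork z-summaries and annualized correlations ---------------
  comp_edges <- if (length(nbs_long$components))
    nbs_long$components[[1]]$pairs else nbs_long$pairs[
      order(abs(nbs_long$t), decreasing = TRUE)[seq_len(10)], , drop = FALSE]
  # healthy reference for disconnection is the no-lesion state: use patients'
  # baseline mean/sd as reference scale when no HC disconnectomes exist
  ref <- reference_stats(disc_base)
  ref$sd[ref$sd == 0] <- NA
  multi <- names(which(table(chp$subject) >= 2))
  ann <- lapply(multi, function(sj) {
    rows <- which(chp$subject == sj)
    r1 <- rows[1]; r2 <- rows[length(rows)]
    yrs <- chp$followup_time[r2] - chp$followup_time[r1]
    if (yrs <= 0) return(NULL)
    z1 <- component_zscore_summary(co$disconnection[[keys[r1]]], ref, comp_edges)
    z2 <- component_zscore_summary(co$disconnection[[keys[r2]]], ref, comp_edges)
    c(dz = annualized_change(z1, z2, yrs),
      dedss = annualized_change(chp$EDSS[r1], chp$EDSS[r2], yrs),
      dtlv = annualized_change(log1p_tlv(chp$TLV[r1]),
                               log1p_tlv(chp$TLV[r2]), yrs))
  })
  ann <- do.call(rbind, Filter(Negate(is.null), ann))
  sp <- spearman(ann[, "dz"], ann[, "dedss"])
  psp <- partial_spearman(ann[, "dz"], ann[, "dedss"], ann[, "dtlv"])
  report$annualized_disc_edss_rho <- sp$rho
  report$annualized_disc_edss_p <- sp$p
  report$annualized_disc_edss_partial_rho <- psp$rho

  # ---- coupling ---------------------------------------------------------
  mind_pw <- co$mind[sprintf("%s_v1", pwb$subject)]
  cg <- coupling(disc_base, mind_pw, "global")
  ce <- coupling(disc_base, mind_pw, "edge")
  cn <- coupling(disc_base, mind_pw, "node")
  report$coupling_global_rho <- cg$rho
  report$coupling_edge_rho <- ce$rho
  report$coupling_node_mean_rho <- mean(cn$rho, na.rm = TRUE)

  # ---- CDP prediction ---------------------------------------------------
  enough <- !anyNA(pwb$CDP) && min(table(pwb$CDP)) >= 5
  if (isTRUE(an$do_predict %||% TRUE) && enough) {
    pcfg <- predict_config(repeats = an$predict_repeats %||% 3,
                           budget = an$predict_budget %||% 8,
                           n_perm = an$predict_n_perm %||% 0,
                           seed = derive_seed(seed, "p"))
    conf <- with(pwb, cbind(age, age2 = age^2, sexM, logTLV))
    pr <- run_nbs_predict(std$Y, pwb$CDP, conf, pcfg,
                          pairs = std$pairs, n_nodes = std$n_nodes)
    report$cdp_accuracy <- pr$accuracy
    report$cdp_sensitivity <- pr$sensitivity
    report$cdp_specificity <- pr$specificity
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

nbs_summary <- function(x) {
  if (!length(x$components)) return(list(n_components = 0))
  c1 <- x$components[[1]]
  list(n_components = length(x$components), largest_edges = c1$n_edges,
       largest_stat_sum = c1$stat_sum, p_fwe = c1$p_fwe, sign = c1$sign)
}
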