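#' Run configuration for the end-to-end pipeline
#'
#' Collects every tunable of the workflow with the study defaults: 1 mm
#' isotropic resampling, 3 mm peritumoral margin, 25-bin entropy map on a
#' 3x3x3 kernel, candidate cluster counts 2-4, the full 851-feature schema,
#' reference-batch ComBat with EB location+scale adjustment, 7:3 stratified
#' split, 5-fold CV, SMOTE k = 5, mRMR pool 30, and one master seed that
#' drives every stage through [derive_seed()].
#'
#' @param phantom a [phantom_config()] (or NULL when reading a cohort from
#'   disk).
#' @param target_mm isotropic voxel size (1).
#' @param margin_mm peritumoral margin (3).
#' @param entropy an [entropy_config()].
#' @param k_candidates candidate habitat counts (2:4).
#' @param schema a [feature_schema()].
#' @param inject_batch logical: plant the phantom batch effects before
#'   harmonization (default TRUE).
#' @param harmonize logical: apply ComBat (default TRUE).
#' @param reference_batch ComBat reference (default NULL = largest batch).
#' @param ratio,folds,mrmr_m,smote_cv model-stage settings.
#' @param seed master seed.
#' @param write_images write per-subject NIfTI triplets into the run
#'   directory (default FALSE).
#' @return list of class `run_config` (with a `config_hash` field).
#' @export
run_config <- function(phantom = phantom_config(), target_mm = 1, margin_mm = 3,
                       entropy = entropy_config(), k_candidates = 2:4,
                       schema = feature_schema(), inject_batch = TRUE,
                       harmonize = TRUE, reference_batch = NULL,
                       ratio = 0.7, folds = 5L, mrmr_m = 30L,
                       smote_cv = "fold", seed = 1L, write_images = FALSE) {
  cfg <- list(phantom = phantom, target_mm = target_mm, margin_mm = margin_mm,
              entropy = entropy, k_candidates = k_candidates, schema = schema,
              inject_batch = inject_batch, harmonize = harmonize,
              reference_batch = reference_batch, ratio = ratio,
              folds = as.integer(folds), mrmr_m = as.integer(mrmr_m),
              smote_cv = smote_cv, seed = as.integer(seed),
              write_images = isTRUE(write_images))
  cfg$config_hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

# a small deterministic hash of the configuration for output provenance
config_hash <- function(cfg) {
  cfg$config_hash <- NULL
  s <- paste(utils::capture.output(utils::str(cfg, give.attr = FALSE)),
             collapse = "")
  sprintf("%08x", derive_seed(0L, s))
}

#' Segment, cluster and label one subject
#'
#' Geometry + habitat stages for a single subject: isotropic resampling,
#' WVOI construction, entropy map and super-voxel table. Clustering itself is
#' cohort-driven (see [run_pipeline()]), so this returns the super-voxel
#' table ready for [select_k()] / [cluster_habitats()].
#'
#' @param subject a phantom subject (or a list with `image`, `gtv_mask`,
#'   `lung_mask`).
#' @param config a [run_config()].
#' @return the subject augmented with `wvoi` (a [expand_gtv()] result) and
#'   `supervoxels`.
#' @export
process_subject <- function(subject, config) {
  rs <- resample_isotropic(subject$image,
                           list(gtv = subject$gtv_mask, lung = subject$lung_mask),
                           target_mm = config$target_mm)
  wv <- expand_gtv(rs$masks$gtv, rs$masks$lung, margin_mm = config$margin_mm)
  em <- entropy_map(rs$volume, wv$wvoi, config$entropy)
  sv <- build_supervoxels(rs$volume, em, wv$wvoi)
  subject$image <- rs$volume
  subject$gtv_mask <- rs$masks$gtv
  subject$lung_mask <- rs$masks$lung
  subject$wvoi <- wv
  subject$supervoxels <- sv
  subject
}

# habitat region masks from a labeling: H1..Hk restricted to the WVOI
habitat_region_masks <- function(subject, labeling) {
  lv <- habitat_label_volume(labeling, subject$supervoxels)
  masks <- list(WVOI = subject$wvoi$wvoi)
  for (h in seq_len(labeling$k)) {
    masks[[paste0("H", h)]] <- region_mask(lv == h, subject$image$spacing_mm,
                                           subject$image$origin)
  }
  masks
}

#' Pivot a long subject-x-region feature table to one wide row per subject
#'
#' Region names become column prefixes (`WVOI_`, `H1_`, `H2_`, ...).
#'
#' @param table an [extract_cohort()] feature table.
#' @return wide data.frame with `subject_id`, `grade`, `batch` and prefixed
#'   feature columns; attribute `feature_names` lists them.
#' @export
pivot_regions <- function(table) {
  fc <- feature_columns(table)
  regions <- unique(table$region)
  subj <- unique(table[, c("subject_id", "grade", "batch")])
  out <- subj
  all_cols <- character(0)
  for (rg in regions) {
    sub <- table[table$region == rg, c("subject_id", fc)]
    names(sub)[-1] <- paste0(rg, "_", fc)
    all_cols <- c(all_cols, names(sub)[-1])
    out <- merge(out, sub, by = "subject_id", sort = FALSE)
  }
  out <- out[order(out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "feature_names") <- all_cols
  out
}

#' Run the full habitat-radiomics pipeline on a phantom cohort
#'
#' Orchestrates phantom generation, geometry, habitat clustering with
#' cohort-wide k selection, feature extraction from WVOI and the two
#' habitats, optional planted batch effects, per-step ComBat harmonization
#' of the concatenated radiomic columns (fitted once per step before the
#' split), two-step model training and evaluation. Writes every stage's
#' tables into `out_dir` and returns the in-memory results. Deterministic
#' given `config$seed`; rerunning with the same config reproduces every
#' artifact.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created; default a tempdir subdir).
#' @param subjects optional pre-generated cohort (default: generate from
#'   `config$phantom`).
#' @return list of class `pipeline_run`: `subjects`, `k_selection`,
#'   `features_long`, `wide_raw`, `wide` (per-step harmonized tables),
#'   `combat` (per-step models), `models`, `report`, `clinical_screen`,
#'   `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         subjects = NULL) {
  if (is.null(out_dir))
    out_dir <- file.path(tempdir(), paste0("habicat-run-", config$config_hash))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[habicat] ", ...)

  if (is.null(subjects)) {
    log_msg("generating phantom cohort")
    ph <- config$phantom
    ph$seed <- derive_seed(config$seed, "phantom")
    subjects <- generate_cohort(ph)
  }
  if (config$write_images) write_cohort(subjects, file.path(out_dir, "images"))

  log_msg("geometry + entropy maps for ", length(subjects), " subjects")
  subjects <- lapply(subjects, process_subject, config = config)

  log_msg("habitat clustering (k candidates: ",
          paste(config$k_candidates, collapse = ","), ")")
  sv_list <- lapply(subjects, `[[`, "supervoxels")
  ks <- select_k(sv_list, candidates = config$k_candidates,
                 seed = derive_seed(config$seed, "cluster"))
  utils::write.csv(ks$metrics, file.path(out_dir, "cluster_metrics.csv"),
                   row.names = FALSE)
  for (i in seq_along(subjects)) {
    subjects[[i]]$habitat_labeling <- ks$labelings[[i]]
    subjects[[i]]$region_masks <- habitat_region_masks(subjects[[i]],
                                                       ks$labelings[[i]])
  }

  # regions entering the models: the WVOI and the two brightest habitats
  # (any additional, darker habitat — e.g. a ring-dominated cluster when
  # k > 2 is selected — is labeled but not extracted)
  regions <- intersect(c("WVOI", "H1", "H2"), names(subjects[[1]]$region_masks))
  log_msg("extracting ", length(config$schema$feature_names), " features x ",
          length(regions), " regions")
  features_long <- extract_cohort(subjects, regions = regions,
                                  schema = config$schema)
  if (config$inject_batch)
    features_long <- inject_batch_effects(features_long, config$phantom)
  write_feature_table(features_long, file.path(out_dir, "features_long.csv"))

  wide <- pivot_regions(features_long)
  clin <- cohort_clinical_table(subjects)
  clinical_cols <- setdiff(names(clin), c("subject_id", "grade", "batch"))
  wide <- merge(wide, clin[, c("subject_id", clinical_cols)],
                by = "subject_id", sort = FALSE)
  attr(wide, "feature_names") <- setdiff(names(wide),
                                         c("subject_id", "grade", "batch",
                                           clinical_cols))
  wide_raw <- wide

  combat_models <- list()
  tables <- list(model1 = wide, model2 = wide[wide$grade %in% c(1, 2), ])
  if (config$harmonize) {
    log_msg("ComBat harmonization (reference batch = ",
            if (is.null(config$reference_batch)) "largest" else
              config$reference_batch, ")")
    for (stp in names(tables)) {
      tb <- tables[[stp]]
      attr(tb, "feature_names") <- attr(wide, "feature_names")
      cm <- fit_combat(tb, reference_batch = config$reference_batch)
      combat_models[[stp]] <- cm
      tables[[stp]] <- apply_combat(cm, tb)
      attr(tables[[stp]], "feature_names") <- attr(wide, "feature_names")
    }
  }

  log_msg("training two-step classifiers")
  models <- train_two_step(tables, clinical_cols = clinical_cols,
                           ratio = config$ratio, folds = config$folds,
                           mrmr_m = config$mrmr_m,
                           seed = derive_seed(config$seed, "model"),
                           smote_cv = config$smote_cv)
  report <- evaluate_two_step(models, tables)
  write_report(report, out_dir)

  screen <- clinical_spearman(clin[, clinical_cols], clin$grade)
  utils::write.csv(screen, file.path(out_dir, "clinical_spearman.csv"),
                   row.names = FALSE)

  jsonlite::write_json(list(config_hash = config$config_hash,
                            seed = config$seed, k = ks$k,
                            schema_version = config$schema$version),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(list(subjects = subjects, k_selection = ks,
                 features_long = features_long, wide_raw = wide_raw,
                 wide = tables, combat = combat_models, models = models,
                 report = report, clinical_screen = screen,
                 config = config, out_dir = out_dir),
            class = "pipeline_run")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror [run_config()] arguments; `phantom` and `entropy`
#' sub-maps are passed to their constructors.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("read_run_config needs the 'yaml' package")
  y <- yaml::read_yaml(path)
  if (!is.null(y$phantom)) y$phantom <- do.call(phantom_config, y$phantom)
  if (!is.null(y$entropy)) y$entropy <- do.call(entropy_config, y$entropy)
  if (!is.null(y$schema)) y$schema <- do.call(feature_schema, y$schema)
  do.call(run_config, y)
}
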