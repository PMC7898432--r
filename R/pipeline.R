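PIPELINE_DEFAULTS <- list(
  simulate = TRUE,
  genotypes_path = NULL, genotypes_format = "vcf",
  phenotypes_path = NULL, annotation_path = NULL,
  mother = "TA", father = "KP",
  n_lg = 5L, markers_per_lg = 200L, lg_length_bp = 16400000,
  lg_length_cM = 100, n_progeny = 104L,
  frac_maternal_informative = 0.4, frac_paternal_informative = 0.4,
  frac_both_het = 0.1, missing_rate = 0.1, genotype_error_rate = 0.01,
  baseline = 400, noise_sd = 80,
  min_run = 3L, n_perm = 999L, threshold = 0.001, max_gap_bp = 1e6,
  min_info_frac = 0.5, prefixes = c("TA", "KP"),
  gene_rule = "start-in-region",
  seed = 1L)

#' Build a validated pipeline configuration
#'
#' Parameters default to the values documented on each stage function; a
#' demo-scale simulated population (5 linkage groups) is generated when no
#' input paths are given. Unknown keys are rejected. Configurations can
#' also be loaded from a YAML file.
#'
#' @param ... parameter overrides (see `ptxqtl:::PIPELINE_DEFAULTS` for the
#'   full key set).
#' @param file optional YAML file whose keys are applied before `...`.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- PIPELINE_DEFAULTS
  apply_over <- function(cfg, over, src) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) {
      stop("unknown configuration key(s) in ", src, ": ",
           paste(bad, collapse = ", "))
    }
    cfg[names(over)] <- over
    cfg
  }
  if (!is.null(file)) cfg <- apply_over(cfg, yaml::read_yaml(file), file)
  over <- list(...)
  if (length(over)) cfg <- apply_over(cfg, over, "arguments")
  if (!cfg$simulate) {
    for (need in c("genotypes_path", "phenotypes_path")) {
      if (is.null(cfg[[need]])) {
        stop("configuration error: simulation disabled and `", need,
             "` not set")
      }
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full pseudo-testcross QTL pipeline
#'
#' Orchestrates simulate/load -> marker classification -> phasing ->
#' breakpoints -> association scans (both parents) -> QTL regions ->
#' diplotype calls and effect tests -> candidate genes (when an annotation
#' is supplied). All stage outputs are written as plain-text tables under
#' `out_dir` together with a JSON run manifest recording parameters,
#' derived seeds and per-stage record counts. Given the same configuration
#' and seed the outputs are byte-identical. A failing stage raises a
#' condition of class `pipeline_stage_error` naming the stage.
#'
#' @param config a [pipeline_config()] (or a YAML path).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- pipeline_config(file = config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(structure(class = c("pipeline_stage_error", "error", "condition"),
                     list(message = sprintf("stage '%s' failed: %s", name,
                                            conditionMessage(e)),
                          call = NULL, stage = name)))
    })
  }
  counts <- list()

  dat <- stage("input", {
    if (config$simulate) {
      sc <- sim_config(
        n_lg = config$n_lg, markers_per_lg = config$markers_per_lg,
        lg_length_bp = config$lg_length_bp,
        lg_length_cM = config$lg_length_cM, n_progeny = config$n_progeny,
        frac_maternal_informative = config$frac_maternal_informative,
        frac_paternal_informative = config$frac_paternal_informative,
        frac_both_het = config$frac_both_het,
        missing_rate = config$missing_rate,
        genotype_error_rate = config$genotype_error_rate,
        seed = config$seed)
      qtls <- Filter(function(q) q$lg %in% lg_name(seq_len(sc$n_lg)),
                     default_qtls(sc$lg_length_bp))
      pop <- simulate_population(sc, qtls = qtls,
                                 baseline = config$baseline,
                                 noise_sd = config$noise_sd)
      write_genotypes_vcf(pop$geno, file.path(out_dir, "genotypes.vcf"))
      write_phenotypes(pop$pheno, file.path(out_dir, "phenotypes.tsv"))
      list(geno = pop$geno, pheno = pop$pheno, truth = pop$truth)
    } else {
      geno <- if (identical(config$genotypes_format, "vcf")) {
        read_genotypes_vcf(config$genotypes_path, config$mother,
                           config$father)
      } else {
        read_genotypes_tsv(config$genotypes_path, config$mother,
                           config$father)
      }
      list(geno = geno,
           pheno = read_phenotypes(config$phenotypes_path, geno),
           truth = NULL)
    }
  })
  counts$markers <- nrow(dat$geno$markers)
  counts$individuals <- length(dat$geno$individuals)
  counts$phenotyped <- nrow(dat$pheno)

  classes <- stage("classify", classify_markers(dat$geno))
  utils::write.table(classes, file.path(out_dir, "markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts$informative_maternal <- sum(classes$class == "MATERNAL_INFORMATIVE")
  counts$informative_paternal <- sum(classes$class == "PATERNAL_INFORMATIVE")

  tms <- stage("phase", {
    lapply(c(maternal = "maternal", paternal = "paternal"), function(p) {
      phase_parent(raw_transmission(dat$geno, classes, p))
    })
  })
  write_transmissions(tms$maternal,
                      file.path(out_dir, "transmissions_maternal.tsv"))
  write_transmissions(tms$paternal,
                      file.path(out_dir, "transmissions_paternal.tsv"))

  bks <- stage("breakpoints", {
    rbind(detect_breakpoints(tms$maternal, config$min_run),
          detect_breakpoints(tms$paternal, config$min_run))
  })
  utils::write.table(bks, file.path(out_dir, "breakpoints.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts$breakpoints <- nrow(bks)

  assoc <- stage("association", {
    rbind(
      assoc_scan(dat$pheno, tms$maternal, n_perm = config$n_perm,
                 seed = derive_seed(config$seed, "perm_maternal")),
      assoc_scan(dat$pheno, tms$paternal, n_perm = config$n_perm,
                 seed = derive_seed(config$seed, "perm_paternal")))
  })
  utils::write.table(assoc, file.path(out_dir, "assoc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  regions <- stage("regions", {
    define_regions(assoc, threshold = config$threshold,
                   max_gap_bp = config$max_gap_bp)
  })
  utils::write.table(as.data.frame(regions),
                     file.path(out_dir, "regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts$qtl_regions <- nrow(regions)

  diplo <- stage("diplotypes", {
    lapply(seq_len(nrow(regions)), function(i) {
      reg <- regions[i, ]
      calls <- call_region_diplotype(tms$maternal, tms$paternal, reg,
                                     config$min_info_frac, config$prefixes,
                                     config$min_run)
      rep <- diplotype_effect_test(calls, dat$pheno)
      safe <- gsub("[^A-Za-z0-9]+", "_", reg$region_id)
      utils::write.table(calls,
                         file.path(out_dir, sprintf("diplotypes_%s.tsv", safe)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(region = reg$region_id, groups = rep$groups,
             anova = rep$anova, tukey = rep$tukey,
             n_recombinant = rep$n_recombinant, n_unknown = rep$n_unknown,
             reason = rep$reason),
        file.path(out_dir, sprintf("effects_%s.json", safe)),
        auto_unbox = TRUE, digits = NA, null = "null")
      list(region = reg$region_id, calls = calls, report = rep)
    })
  })

  genes <- NULL
  if (!is.null(config$annotation_path)) {
    genes <- stage("genes", {
      gt <- if (grepl("\\.gff3?$", config$annotation_path)) {
        read_genes_gff3(config$annotation_path)
      } else {
        read_gene_table(config$annotation_path)
      }
      lapply(seq_len(nrow(regions)), function(i) {
        reg <- regions[i, ]
        hit <- genes_in_region(gt, reg, config$gene_rule)
        safe <- gsub("[^A-Za-z0-9]+", "_", reg$region_id)
        utils::write.table(hit,
                           file.path(out_dir, sprintf("genes_%s.tsv", safe)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        hit
      })
    })
  }

  manifest <- list(
    package = "ptxqtl",
    version = as.character(utils::packageVersion("ptxqtl")),
    parameters = unclass(config),
    derived_seeds = list(
      parents = derive_seed(config$seed, "parents"),
      progeny = derive_seed(config$seed, "progeny"),
      trait = derive_seed(config$seed, "trait"),
      perm_maternal = derive_seed(config$seed, "perm_maternal"),
      perm_paternal = derive_seed(config$seed, "perm_paternal")),
    counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(geno = dat$geno, pheno = dat$pheno, truth = dat$truth,
                 classes = classes, transmissions = tms, breakpoints = bks,
                 assoc = assoc, regions = regions, diplotypes = diplo,
                 genes = genes, manifest = manifest))
}
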