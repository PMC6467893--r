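#' Parameters of the synthetic NSCLC-like cohort
#'
#' Defaults mirror the profiled study's conditions: 131 ADC and 114 SQCC
#' samples, 26 immune signatures (11 adaptive / 12 innate / 3 other), an
#' additive log-scale infiltration shift delta = 2 for infiltrated signature
#' genes, HIGH/MIX/LOW proportions 0.3/0.4/0.3, KRAS mutations enriched in
#' immune HIGH and EGFR in immune LOW ADC, PTEN loss / PIK3CA amplification
#' enriched in LOW+MIX SQCC, a C>A substitution excess in smokers, and
#' exponential survival whose hazard doubles (log-HR = ln 2) outside the
#' immune HIGH group with independent uniform censoring.
#'
#' @param ... named overrides of any default.
#' @return a list of class \code{sim_params}.
#' @export
simulationParams <- function(...) {
  p <- list(
    nAdc = 131L, nSqcc = 114L,
    nGenes = 2000L,
    signatureSize = 15L,
    delta = 2,
    groupProps = c(HIGH = 0.3, MIX = 0.4, LOW = 0.3),
    mixInfiltrationFrac = 0.8,
    driverPrev = list(  # P(mutated | immune group), ADC unless noted
      KRAS = c(HIGH = 0.40, MIX = 0.05, LOW = 0.05),
      EGFR = c(HIGH = 0.10, MIX = 0.30, LOW = 0.50),
      TP53 = c(HIGH = 0.40, MIX = 0.40, LOW = 0.40)),
    ptenLossPrev = c(HIGH = 0.05, MIX = 0.35, LOW = 0.35),   # SQCC
    pik3caAmpPrev = c(HIGH = 0.05, MIX = 0.30, LOW = 0.30),  # SQCC
    smokerProp = 0.6,
    subsProbs = rbind(
      smoker     = c("C>A" = 0.45, "C>G" = 0.10, "C>T" = 0.20,
                     "T>A" = 0.05, "T>C" = 0.15, "T>G" = 0.05),
      `non-smoker` = c("C>A" = 0.25, "C>G" = 0.10, "C>T" = 0.30,
                       "T>A" = 0.05, "T>C" = 0.25, "T>G" = 0.05)),
    meanPassengers = 40,
    readLambda = 30,
    contamFracs = c(low_read = 0.08, syn_utr = 0.12, germline = 0.08,
                    popdb = 0.05, pon = 0.03),
    canonicalFusionRate = 0.04,
    backgroundFusionRate = 0.15,
    baselineHazard = 1 / 800,
    survBeta = log(2),
    censorMax = 2400)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  if (abs(sum(p$groupProps) - 1) > 1e-8)
    stop("group proportions must sum to 1")
  if (p$delta < 0) stop("delta must be >= 0")
  prevs <- c(unlist(p$driverPrev), p$ptenLossPrev, p$pik3caAmpPrev,
             p$contamFracs, p$smokerProp)
  if (any(prevs < 0 | prevs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(abs(rowSums(p$subsProbs) - 1) > 1e-8))
    stop("substitution-class probabilities must sum to 1 per smoking status")
  if (!is.finite(p$survBeta)) stop("survival log-hazard must be finite")
  structure(p, class = "sim_params")
}

# signature names of the canonical 26-signature immune collection
adaptiveSignatures <- c("T_cells", "B_cells", "CD8_T_cells",
                        "Cytotoxic_cells", "TEM", "TCM", "Tfh", "Th1",
                        "Th2", "Th17", "Treg")
innateSignatures <- c("NK_cells", "NK_CD56bright", "NK_CD56dim",
                      "Macrophages", "Monocytes", "DC", "aDC", "iDC",
                      "pDC", "Neutrophils", "Eosinophils", "Mast_cells")
otherSignatures <- c("MDSC", "Angiogenesis", "APM")

markerGenesDefault <- c("IFNG", "CD274", "PDCD1", "CD8A", "CCL4",
                        "PIK3CA", "PTEN")
driverGenesDefault <- c("KRAS", "EGFR", "TP53")

# gene universe: signature blocks first, named marker/driver genes at the end
simGeneUniverse <- function(nGenes) {
  special <- c(markerGenesDefault, driverGenesDefault)
  g <- sprintf("GENE%05d", seq_len(nGenes - length(special)))
  c(g, special)
}

#' The canonical 26-signature immune collection over a simulated universe
#'
#' Disjoint gene blocks of \code{size} genes per signature: 11 adaptive,
#' 12 innate, 3 other (MDSC, angiogenesis, APM).
#'
#' @param genes gene universe (character).
#' @param size genes per signature.
#' @return a \linkS4class{SignatureCollection} of 26 signatures.
#' @export
makeImmuneSignatures <- function(genes, size = 15L) {
  nm <- c(adaptiveSignatures, innateSignatures, otherSignatures)
  if (length(genes) < 26 * size + 10)
    stop("gene universe too small for 26 signatures of size ", size)
  sets <- lapply(seq_along(nm), function(i)
    genes[((i - 1) * size + 1):(i * size)])
  names(sets) <- nm
  category <- setNames(c(rep("adaptive", 11), rep("innate", 12),
                         rep("other", 3)), nm)
  SignatureCollection(sets, category)
}

simTruthLabels <- function(params) {
  n <- params$nAdc + params$nSqcc
  samples <- sprintf("S%03d", seq_len(n))
  histology <- c(rep("ADC", params$nAdc), rep("SQCC", params$nSqcc))
  group <- sample(names(params$groupProps), n, replace = TRUE,
                  prob = params$groupProps)
  smoking <- sample(c("smoker", "non-smoker"), n, replace = TRUE,
                    prob = c(params$smokerProp, 1 - params$smokerProp))
  sigs <- c(adaptiveSignatures, innateSignatures, otherSignatures)
  enrich <- matrix(FALSE, length(sigs), n, dimnames = list(sigs, samples))
  # MIX = the cytotoxic-excluded phenotype: T/B-lineage signatures off,
  # every other compartment infiltrated with prob mixInfiltrationFrac
  cytotoxic_lineage <- c("T_cells", "B_cells", "CD8_T_cells",
                         "Cytotoxic_cells")
  mix_pool <- setdiff(sigs, cytotoxic_lineage)
  for (j in seq_len(n)) {
    if (group[j] == "HIGH") enrich[, j] <- TRUE
    if (group[j] == "MIX") {
      on <- mix_pool[stats::runif(length(mix_pool)) <
                       params$mixInfiltrationFrac]
      enrich[on, j] <- TRUE
    }
  }
  list(samples = samples,
       histology = setNames(histology, samples),
       group = setNames(group, samples),
       smoking = setNames(smoking, samples),
       enrich = enrich)
}

#' Generate the synthetic FPKM expression matrix
#'
#' Log-normal baseline per gene; genes of each infiltrated signature are
#' shifted by \code{delta} on the log scale in that sample, and the immune
#' marker genes (IFNG, PD-L1, PD-1, CD8, CCL4) are co-shifted in immune
#' HIGH samples. SQCC samples with planted PTEN loss / PIK3CA amplification
#' get the corresponding expression shift. Uses the active RNG stream.
#'
#' @param params \code{\link{simulationParams}}.
#' @param truth truth labels (internal structure from
#'   \code{\link{simulateCohort}}).
#' @param signatures the \linkS4class{SignatureCollection} being planted.
#' @param cnvTruth optional data.frame with sample, pten_loss, pik3ca_amp.
#' @return genes x samples FPKM matrix.
#' @export
generateExpression <- function(params, truth, signatures,
                               cnvTruth = NULL) {
  genes <- simGeneUniverse(params$nGenes)
  missing_sig <- setdiff(unique(unlist(geneSets(signatures))), genes)
  if (length(missing_sig))
    stop("signature genes absent from gene universe: ",
         paste(utils::head(missing_sig, 5), collapse = ", "))
  n <- length(truth$samples)
  meanlog <- stats::rnorm(length(genes), 1.5, 1)
  names(meanlog) <- genes
  shift <- matrix(0, length(genes), n, dimnames = list(genes, truth$samples))
  for (sig in signatureNames(signatures)) {
    sg <- geneSets(signatures)[[sig]]
    on <- truth$enrich[sig, ]
    shift[sg, on] <- shift[sg, on] + params$delta
  }
  markers <- c("IFNG", "CD274", "PDCD1", "CD8A", "CCL4")
  hi <- truth$group == "HIGH"
  shift[markers, hi] <- shift[markers, hi] + params$delta
  if (!is.null(cnvTruth)) {
    pl <- cnvTruth$sample[cnvTruth$pten_loss]
    shift["PTEN", pl] <- shift["PTEN", pl] - params$delta
    pa <- cnvTruth$sample[cnvTruth$pik3ca_amp]
    shift["PIK3CA", pa] <- shift["PIK3CA", pa] + params$delta
  }
  noise <- matrix(stats::rnorm(length(genes) * n, 0, 0.7), length(genes), n)
  expr <- exp(meanlog + shift + noise)
  dimnames(expr) <- list(genes, truth$samples)
  expr
}

# fixed gene model used by the CNV plant and the gene-level CNV summaries
simGeneModel <- function() {
  data.frame(
    gene = c("PTEN", "PIK3CA", "KRAS", "EGFR", "CDKN2A"),
    chrom = c("chr10", "chr3", "chr12", "chr7", "chr9"),
    start = c(89.60e6, 178.80e6, 25.35e6, 55.00e6, 21.90e6),
    end = c(89.80e6, 179.00e6, 25.45e6, 55.30e6, 22.10e6),
    stringsAsFactors = FALSE)
}

#' Generate synthetic multi-caller variants, segments and fusion candidates
#'
#' Driver mutations follow the group-conditional prevalence table; every
#' somatic variant is emitted by 1-3 callers with Poisson-distributed
#' supporting reads; known fractions of matched-germline, population-
#' database-flagged, panel-of-normals, synonymous/UTR and low-read (< 8)
#' contaminants are planted and recorded in the ground truth so the filter
#' cascade's per-stage counts are exactly predictable. Substitution classes
#' are drawn per smoking status (C>A excess in smokers). Segments encode
#' planted PTEN loss and PIK3CA amplification in SQCC. Uses the active RNG
#' stream.
#'
#' @inheritParams generateExpression
#' @return list: calls (per-caller long table), germlineKeys, ponKeys,
#'   segments, fusions, knowledge, truth tables (variantClasses, drivers,
#'   cnv).
#' @export
generateGenomics <- function(params, truth) {
  n <- length(truth$samples)
  callers <- c("mutA", "mutB", "mutC")
  classes <- c("somatic", names(params$contamFracs))
  probs <- c(1 - sum(params$contamFracs), params$contamFracs)
  rows <- list()
  classTruth <- list()
  germlineKeys <- character()
  ponKeys <- character()
  drivers <- data.frame(sample = truth$samples, KRAS = FALSE, EGFR = FALSE,
                        TP53 = FALSE, stringsAsFactors = FALSE)
  driverPos <- c(KRAS = 25398284, EGFR = 55259515, TP53 = 7577120)
  driverChrom <- c(KRAS = "chr12", EGFR = "chr7", TP53 = "chr17")
  cnv <- data.frame(sample = truth$samples, pten_loss = FALSE,
                    pik3ca_amp = FALSE, stringsAsFactors = FALSE)
  pyr <- list("C>A" = c("C", "A"), "C>G" = c("C", "G"), "C>T" = c("C", "T"),
              "T>A" = c("T", "A"), "T>C" = c("T", "C"), "T>G" = c("T", "G"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (j in seq_len(n)) {
    s <- truth$samples[j]
    grp <- truth$group[j]
    hist <- truth$histology[j]
    srows <- list()
    addVariant <- function(chrom, pos, ref, alt, eff, reads, cls) {
      ncall <- sample(1:3, 1, prob = c(0.2, 0.35, 0.45))
      who <- sample(callers, ncall)
      # the first caller carries the max read depth; others report <= max
      rd <- c(reads, if (ncall > 1)
        pmax(1L, reads - sample(0:5, ncall - 1, replace = TRUE)))
      in_1000g <- in_exac <- FALSE
      if (cls == "popdb") {
        in_1000g <- sample(c(TRUE, FALSE), 1)
        in_exac <- !in_1000g
      }
      srows[[length(srows) + 1L]] <<- data.frame(
        sample_id = s, chrom = unname(chrom), pos = unname(pos),
        ref = ref, alt = alt,
        caller_id = who, supporting_reads = as.integer(rd),
        effect_class = eff,
        popdb_1000g = in_1000g, popdb_exac = in_exac,
        stringsAsFactors = FALSE, row.names = NULL)
      key <- paste(s, unname(chrom), unname(pos), ref, alt, sep = "|")
      if (cls == "germline")
        germlineKeys <<- c(germlineKeys, key)
      if (cls == "pon")
        ponKeys <<- c(ponKeys, paste(chrom, pos, ref, alt, sep = "|"))
      classTruth[[length(classTruth) + 1L]] <<- data.frame(
        sample_id = s, key = key, class = cls, stringsAsFactors = FALSE)
    }
    # drivers (ADC for KRAS/EGFR; TP53 both histologies)
    for (gene in names(params$driverPrev)) {
      if (gene %in% c("KRAS", "EGFR") && hist != "ADC") next
      if (stats::runif(1) < params$driverPrev[[gene]][grp]) {
        drivers[[gene]][j] <- TRUE
        addVariant(driverChrom[gene], driverPos[gene], "G", "T",
                   "nonsynonymous", 8L + stats::rpois(1, params$readLambda - 8),
                   "somatic")
      }
    }
    # passengers with planted contaminant classes
    npass <- stats::rpois(1, params$meanPassengers)
    if (npass > 0) {
      pos <- sample(1e6:2e8, npass)
      cls <- sample(classes, npass, replace = TRUE, prob = probs)
      sub_cls <- sample(colnames(params$subsProbs), npass, replace = TRUE,
                        prob = params$subsProbs[truth$smoking[j], ])
      for (i in seq_len(npass)) {
        ra <- pyr[[sub_cls[i]]]
        if (stats::runif(1) < 0.5) ra <- unname(comp[ra])  # purine strand
        reads <- if (cls[i] == "low_read") sample(1:7, 1) else
          8L + stats::rpois(1, params$readLambda - 8)
        eff <- if (cls[i] == "syn_utr")
          sample(c("synonymous", "UTR"), 1) else "nonsynonymous"
        addVariant("chr1", pos[i], ra[1], ra[2], eff, as.integer(reads),
                   cls[i])
      }
    }
    rows[[j]] <- do.call(rbind, srows)
    # copy-number plant (SQCC)
    if (hist == "SQCC") {
      cnv$pten_loss[j] <- stats::runif(1) < params$ptenLossPrev[grp]
      cnv$pik3ca_amp[j] <- stats::runif(1) < params$pik3caAmpPrev[grp]
    }
  }
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  segments <- simSegments(truth, cnv)
  fus <- simFusions(params, truth)
  list(calls = calls, germlineKeys = unique(germlineKeys),
       ponKeys = unique(ponKeys), segments = segments,
       fusions = fus$candidates, knowledge = fus$knowledge,
       variantClasses = do.call(rbind, classTruth), drivers = drivers,
       cnv = cnv, geneModel = simGeneModel())
}

simSegments <- function(truth, cnv) {
  gm <- simGeneModel()
  rows <- list()
  for (j in seq_along(truth$samples)) {
    s <- truth$samples[j]
    for (ci in seq_len(nrow(gm))) {
      chrom <- gm$chrom[ci]
      lr0 <- stats::rnorm(1, 0, 0.05)
      lr_gene <- lr0
      if (gm$gene[ci] == "PTEN" && cnv$pten_loss[j])
        lr_gene <- sample(c(-1.5, -0.6), 1)
      if (gm$gene[ci] == "PIK3CA" && cnv$pik3ca_amp[j])
        lr_gene <- sample(c(1.2, 0.5), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, chrom = chrom,
        start = c(1, gm$start[ci], gm$end[ci] + 1),
        end = c(gm$start[ci] - 1, gm$end[ci], 2e8),
        log2_ratio = c(lr0, lr_gene, lr0),
        n_probes = c(500L, 50L, 500L), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

simFusions <- function(params, truth) {
  canon <- data.frame(
    gene5 = c("EML4", "CCDC6", "CD74", "KIF5B", "FGFR3"),
    gene3 = c("ALK", "RET", "ROS1", "RET", "TACC3"),
    stringsAsFactors = FALSE)
  census <- c("ALK", "RET", "ROS1", "EML4", "CD74", "KIF5B", "FGFR3",
              "TACC3", "EGFR", "KRAS", "TP53")
  rows <- list()
  for (j in seq_along(truth$samples)) {
    s <- truth$samples[j]
    if (truth$histology[j] == "ADC" &&
        stats::runif(1) < params$canonicalFusionRate) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, gene5 = "EML4", gene3 = "ALK",
        junction_reads = 8L + stats::rpois(1, 10),
        spanning_mates = 4L + stats::rpois(1, 6),
        callers = "defuse;tophat-fusion;fusioncatcher",
        stringsAsFactors = FALSE)
    }
    if (stats::runif(1) < params$backgroundFusionRate) {
      gp <- sprintf("GENE%05d", sample(1:500, 2))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, gene5 = gp[1], gene3 = gp[2],
        junction_reads = sample(1:3, 1), spanning_mates = sample(0:2, 1),
        callers = sample(c("defuse", "tophat-fusion", "fusioncatcher"), 1),
        stringsAsFactors = FALSE)
    }
  }
  cand <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), gene5 = character(),
               gene3 = character(), junction_reads = integer(),
               spanning_mates = integer(), callers = character(),
               stringsAsFactors = FALSE)
  rownames(cand) <- NULL
  list(candidates = cand,
       knowledge = fusionKnowledge(canon, census))
}

#' Generate the synthetic clinical table with planted survival structure
#'
#' Event times are exponential with log-hazard \code{survBeta} for samples
#' outside the immune HIGH group (so HIGH survives longer); censoring is
#' independent uniform on (0, \code{censorMax}), which allows times beyond
#' 1200 days so the censoring-horizon rule is exercised. Uses the active
#' RNG stream.
#'
#' @inheritParams generateExpression
#' @return clinical data.frame: sample, histology, age, sex, stage, smoking,
#'   os_days, os_event, treatment.
#' @export
generateSurvival <- function(params, truth) {
  if (!is.finite(params$survBeta)) stop("survival log-hazard must be finite")
  n <- length(truth$samples)
  z <- as.numeric(truth$group != "HIGH")
  rate <- params$baselineHazard * exp(params$survBeta * z)
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::runif(n, 0, params$censorMax)
  data.frame(
    sample = truth$samples,
    histology = unname(truth$histology),
    age = pmin(85, pmax(30, round(stats::rnorm(n, 62, 9)))),
    sex = sample(c("F", "M"), n, replace = TRUE),
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                   prob = c(0.35, 0.25, 0.3, 0.1)),
    smoking = unname(truth$smoking),
    os_days = round(pmin(t_event, t_cens), 1),
    os_event = as.integer(t_event <= t_cens),
    treatment = sample(c("surgery_only", "adjuvant_chemo"), n,
                       replace = TRUE),
    stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic NSCLC-like cohort
#'
#' Draws truth labels (immune group, per-signature infiltration flags,
#' smoking), then expression, genomics (multi-caller variants with planted
#' contaminants, segments, fusion candidates) and clinical/survival tables,
#' all from a single seeded RNG stream: the same seed always reproduces the
#' identical cohort.
#'
#' @param params \code{\link{simulationParams}}.
#' @param seed integer seed.
#' @return list of class \code{synthetic_cohort}: expression, signatures,
#'   calls, germlineKeys, ponKeys, segments, geneModel, fusions, knowledge,
#'   clinical, and \code{truth} (group, enrich flags, smoking, variant
#'   classes, drivers, cnv).
#' @export
simulateCohort <- function(params = simulationParams(), seed = 1L) {
  withSeed(seed, {
    truth <- simTruthLabels(params)
    gen <- generateGenomics(params, truth)
    expr <- generateExpression(params, truth,
                               makeImmuneSignatures(
                                 simGeneUniverse(params$nGenes),
                                 params$signatureSize),
                               cnvTruth = gen$cnv)
    clinical <- generateSurvival(params, truth)
    structure(list(
      expression = expr,
      signatures = makeImmuneSignatures(simGeneUniverse(params$nGenes),
                                        params$signatureSize),
      calls = gen$calls, germlineKeys = gen$germlineKeys,
      ponKeys = gen$ponKeys, segments = gen$segments,
      geneModel = gen$geneModel, fusions = gen$fusions,
      knowledge = gen$knowledge, clinical = clinical,
      truth = list(group = truth$group, enrich = truth$enrich,
                   smoking = truth$smoking, histology = truth$histology,
                   variantClasses = gen$variantClasses,
                   drivers = gen$drivers, cnv = gen$cnv)),
      class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", ncol(x$expression), "samples,",
      nrow(x$expression), "genes\n")
  cat("  histology:", paste(names(table(x$truth$histology)),
                            table(x$truth$histology), collapse = ", "), "\n")
  cat("  immune groups:", paste(names(table(x$truth$group)),
                                table(x$truth$group), collapse = ", "), "\n")
  cat("  variant call rows:", nrow(x$calls),
      "| fusion candidates:", nrow(x$fusions), "\n")
  invisible(x)
}

#' Write every table of a synthetic cohort to standard-format files
#'
#' Expression TSV, GMT + category sidecar, one VCF per caller and sample
#' under \code{calls/<caller>/}, SEG, clinical TSV and a \code{truth.tsv}
#' with the planted labels.
#'
#' @param cohort a \code{\link{simulateCohort}} result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpressionMatrix(cohort$expression, file.path(dir, "expression.tsv"))
  writeGeneSets(cohort$signatures, file.path(dir, "signatures.gmt"),
                file.path(dir, "signature_categories.tsv"))
  writeSegTable(cohort$segments, file.path(dir, "copynumber.seg"))
  writeClinicalTable(cohort$clinical, file.path(dir, "clinical.tsv"))
  utils::write.table(cohort$fusions, file.path(dir, "fusion_candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(cohort$truth$group),
               group = unname(cohort$truth$group),
               histology = unname(cohort$truth$histology),
               smoking = unname(cohort$truth$smoking)),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  for (cl in unique(cohort$calls$caller_id)) {
    cdir <- file.path(dir, "calls", cl)
    dir.create(cdir, showWarnings = FALSE, recursive = TRUE)
    sub <- cohort$calls[cohort$calls$caller_id == cl, ]
    for (s in unique(sub$sample_id))
      writeVariantCalls(sub[sub$sample_id == s, ],
                        file.path(cdir, paste0(s, ".vcf")))
  }
  invisible(dir)
}
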