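test_that("loading correction centres each channel at median zero", {
  des <- toyDesign(nBio = 1, nTech = 2, temperatures = "control")
  pe <- toyPe(peptide_id = c("p1", "p2", "p1", "p2"),
              gene_ids = c("g1", "g2", "g1", "g2"),
              sample_id = rep(des$sample_id, each = 2),
              intensity = c(4, 16, 8, 8), design = des)
  out <- log2LoadingCorrect(pe)
  pep <- peptideData(out)
  ch1 <- pep$intensity[pep$sample_id == des$sample_id[1]]
  expect_equal(sort(ch1), c(-1, 1))  # log2 {4,16} = {2,4}, median 3
  expect_equal(processingStage(out), "normalized")
  meds <- tapply(pep$intensity, pep$sample_id, median)
  expect_equal(as.numeric(meds), rep(0, 2))
})

test_that("nonpositive intensities are rejected naming the row", {
  des <- toyDesign(nBio = 1, nTech = 1, temperatures = "control")
  pe <- toyPe("p1", "g1", des$sample_id[1], 5, des)
  pe@peptides$intensity <- -2  # bypass constructor validity
  expect_error(log2LoadingCorrect(pe), "p1")
})

test_that("channels without peptides are dropped with a warning", {
  des <- toyDesign(nBio = 1, nTech = 2, temperatures = "control")
  pe <- toyPe(c("p1", "p2"), c("g1", "g2"), rep(des$sample_id[1], 2),
              c(2, 8), des)
  expect_warning(out <- log2LoadingCorrect(pe), des$sample_id[2])
  expect_false(des$sample_id[2] %in% sampleDesign(out)$sample_id)
})

test_that("both normalization steps are idempotent", {
  study <- smallStudy(nGenes = 50, seed = 6)
  norm <- log2LoadingCorrect(study$peptides)
  expect_equal(peptideData(loadingCorrect(norm)), peptideData(norm))
  pol <- medianPolishGenes(norm)
  expect_equal(peptideData(medianPolishGenes(pol)), peptideData(pol))
})

test_that("median polish matches hand-computed run summaries", {
  # one channel per run, three runs
  des <- data.frame(sample_id = c("s1", "s2", "s3"), assay = "protein",
                    strain = "CC7", temperature = "control",
                    bio_rep = 1:3, tech_rep = 1,
                    run = c("run1", "run2", "run3"),
                    stringsAsFactors = FALSE)
  # gene g1: run summaries {-2, 0, +2} -> offset median 0, values unchanged
  # gene g2: run summaries {1, 1, 1} -> all values reduced by 1
  pep <- data.frame(
    peptide_id = rep(c("a", "b"), each = 3),
    gene_ids = rep(c("g1", "g2"), each = 3),
    run = rep(c("run1", "run2", "run3"), 2),
    sample_id = rep(c("s1", "s2", "s3"), 2),
    intensity = c(-2, 0, 2, 1, 1, 1), stringsAsFactors = FALSE)
  pe <- PeptideExperiment(pep, des, stage = "normalized")
  out <- peptideData(medianPolishGenes(pe))
  expect_equal(out$intensity[out$gene_ids == "g1"], c(-2, 0, 2))
  expect_equal(out$intensity[out$gene_ids == "g2"], c(0, 0, 0))
})

test_that("after polish every gene's cross-run summary median is zero", {
  study <- smallStudy(nGenes = 80, seed = 12)
  pol <- peptideData(medianPolishGenes(log2LoadingCorrect(study$peptides)))
  # brute-force recomputation of run summaries
  for (g in unique(pol$gene_ids)[1:40]) {
    sub <- pol[pol$gene_ids == g, ]
    rs <- tapply(sub$intensity, sub$run, median)
    expect_equal(unname(median(rs)), 0, tolerance = 1e-12)
  }
})

test_that("loading correction removes simulated per-channel offsets", {
  study <- smallStudy(nGenes = 400, seed = 21, loadingOffsetSd = 1)
  raw <- peptideData(study$peptides)
  pre <- tapply(log2(raw$intensity), raw$sample_id, median)
  expect_gt(sd(pre), 0.6)   # offsets sd 1 dominate pre-correction medians
  expect_lt(sd(pre), 1.5)
  post <- peptideData(log2LoadingCorrect(study$peptides))
  meds <- tapply(post$intensity, post$sample_id, median)
  expect_lt(max(abs(meds)), 1e-9)
})

test_that("detection filter applies the >=2 technical / >=1 biological rule", {
  des <- toyDesign(nBio = 2, nTech = 2, temperatures = "control")
  ids <- des$sample_id  # b1_t1 b1_t2 b2_t1 b2_t2 (one group)
  pep <- data.frame(
    peptide_id = c("p1", "p2", "p2", "p3", "p3", "p4", "p4", "p4"),
    gene_ids = "g1", run = "run1",
    sample_id = c(ids[1], ids[1], ids[2], ids[1], ids[3],
                  ids[1], ids[2], ids[3]),
    intensity = 2, stringsAsFactors = FALSE)
  # detections per peptide: p1: 1 channel; p2: 2 (same bio rep);
  # p3: 2 (different bio reps); p4: 3; p5: 0  -> 3 retained
  pe <- PeptideExperiment(pep, des, stage = "raw")
  kept <- unique(peptideData(filterDetection(pe))$peptide_id)
  expect_setequal(kept, c("p2", "p3", "p4"))
  # strict reading: >=2 technical channels within a single biological rep
  keptStrict <- unique(peptideData(filterDetection(pe, strict = TRUE))$peptide_id)
  expect_setequal(keptStrict, c("p2", "p4"))
})

test_that("the filter decides per strain-temperature group", {
  des <- toyDesign(nBio = 2, nTech = 2)
  ctl <- des$sample_id[des$temperature == "control"]
  str <- des$sample_id[des$temperature == "stress"]
  pep <- data.frame(peptide_id = "p1", gene_ids = "g1", run = "run1",
                    sample_id = c(ctl[1:2], str[1]), intensity = 2,
                    stringsAsFactors = FALSE)
  pe <- PeptideExperiment(pep, des, stage = "raw")
  out <- peptideData(filterDetection(pe))
  expect_setequal(out$sample_id, ctl[1:2])  # kept in control, dropped in stress
})

test_that("unknown sample ids make the filter fail hard", {
  des <- toyDesign(nBio = 2, nTech = 2)
  pe <- toyPe("p1", "g1", des$sample_id[1], 2, des)
  pe@peptides$sample_id <- "nonexistent"
  pe@peptides$run <- "run1"
  expect_error(filterDetection(pe), "nonexistent")
})

test_that("relative expression summaries use the sample-sd standard error", {
  des <- toyDesign(nBio = 1, nTech = 2, temperatures = "control")
  pe <- toyPe(c("p1", "p1"), "g1", des$sample_id, c(-1, 1), des,
              stage = "polished")
  out <- summarizeRelExpr(pe)
  expect_equal(out$mean_log2, 0)
  expect_equal(out$se_log2, 1)  # sd({-1,1}) = sqrt(2); se = sqrt(2)/sqrt(2)
  expect_equal(out$n_tech, 2)
  expect_equal(out$n_bio, 1)
  # single value -> se 0
  pe1 <- toyPe("p1", "g1", des$sample_id[1], 0.7, des, stage = "polished")
  expect_equal(summarizeRelExpr(pe1)$se_log2, 0)
})

test_that("relative expression is invariant to per-channel offsets", {
  # the reference-free contract: scaling one channel's raw intensities
  # leaves all downstream group differences unchanged
  study <- smallStudy(nGenes = 60, seed = 13)
  run <- function(st) {
    pe <- filterDetection(medianPolishGenes(log2LoadingCorrect(st)))
    summarizeRelExpr(pe)
  }
  base <- run(study$peptides)
  shifted <- study$peptides
  ch <- shifted@peptides$sample_id == sampleDesign(shifted)$sample_id[1]
  shifted@peptides$intensity[ch] <- shifted@peptides$intensity[ch] * 2^1.7
  alt <- run(shifted)
  diffOf <- function(r) {
    w <- reshape(r[, c("gene_id", "strain", "temperature", "mean_log2")],
                 idvar = c("gene_id", "strain"), timevar = "temperature",
                 direction = "wide")
    setNames(w$mean_log2.stress - w$mean_log2.control,
             paste(w$gene_id, w$strain))
  }
  d0 <- diffOf(base); d1 <- diffOf(alt)
  shared <- intersect(names(d0), names(d1))
  expect_gt(length(shared), 50)
  expect_equal(d0[shared], d1[shared], tolerance = 1e-9)
})

test_that("per-gene shifts cancel in across-group differences", {
  # the median polish removes any constant added to one gene in every run
  study <- smallStudy(nGenes = 40, seed = 14)
  norm <- log2LoadingCorrect(study$peptides)
  g <- "gene00005"
  run <- function(pe) {
    r <- summarizeRelExpr(filterDetection(medianPolishGenes(pe)))
    r[r$gene_id == g, ]
  }
  base <- run(norm)
  shifted <- norm
  rows <- shifted@peptides$gene_ids == g
  shifted@peptides$intensity[rows] <- shifted@peptides$intensity[rows] + 3
  alt <- run(shifted)
  key0 <- order(paste(base$strain, base$temperature))
  key1 <- order(paste(alt$strain, alt$temperature))
  expect_equal(diff(base$mean_log2[key0]), diff(alt$mean_log2[key1]),
               tolerance = 1e-9)
  # and the polished values themselves are identical (offset fully absorbed)
  expect_equal(base$mean_log2, alt$mean_log2, tolerance = 1e-9)
})

test_that("zero-noise group differences recover the true protein effect", {
  # exact on a constructed table where the affected gene cannot move the
  # channel medians (many unaffected filler genes around it)
  des <- toyDesign(nBio = 2, nTech = 1)
  ids <- des$sample_id
  filler <- expand.grid(peptide_id = paste0("f", 1:9), sample_id = ids,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  filler$gene_ids <- sub("f", "gf", filler$peptide_id)
  # middle order statistics pinned at 3 so the target cannot move the
  # channel median wherever it lands
  filler$intensity <- 2^rep(c(0, 1, 2, 3, 3, 3, 3, 4, 5),
                            times = length(ids))
  delta <- 0.9
  target <- data.frame(peptide_id = "t1", sample_id = ids,
                       gene_ids = "gt",
                       intensity = 2^(3 + delta *
                         (des$temperature[match(ids, des$sample_id)] ==
                          "stress")),
                       stringsAsFactors = FALSE)
  pep <- rbind(filler, target)
  pep$run <- "run1"
  pe <- PeptideExperiment(pep[, c("peptide_id", "gene_ids", "run",
                                  "sample_id", "intensity")], des)
  r <- summarizeRelExpr(filterDetection(medianPolishGenes(
    log2LoadingCorrect(pe))))
  r <- r[r$gene_id == "gt", ]
  expect_equal(r$mean_log2[r$temperature == "stress"] -
               r$mean_log2[r$temperature == "control"], delta,
               tolerance = 1e-12)

  # near-exact on a zero-noise simulation (channel medians move by at most
  # the median displacement the affected genes induce)
  study <- smallStudy(nGenes = 300, seed = 15, noiseSdProtein = 0,
                      detectProb = 1, deFraction = 0.05)
  r <- summarizeRelExpr(filterDetection(medianPolishGenes(
    log2LoadingCorrect(study$peptides))))
  for (s in study$config@strains) {
    sub <- r[r$strain == s, ]
    w <- reshape(sub[, c("gene_id", "temperature", "mean_log2")],
                 idvar = "gene_id", timevar = "temperature",
                 direction = "wide")
    est <- w$mean_log2.stress - w$mean_log2.control
    expect_lt(max(abs(est - study$truth$effProtein[w$gene_id, s])), 0.1)
  }
})

test_that("channel matrix averages peptides per gene and keeps the design", {
  des <- toyDesign(nBio = 1, nTech = 1, temperatures = "control")
  pe <- toyPe(c("p1", "p2"), c("g1", "g1"), rep(des$sample_id, 2),
              c(1, 3), des, stage = "polished")
  m <- proteinChannelMatrix(pe)
  expect_equal(m["g1", des$sample_id], 2, ignore_attr = TRUE)
  expect_equal(attr(m, "design")$sample_id, des$sample_id)
})
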