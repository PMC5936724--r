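# In-code fixtures shared across test files.

# A small protein-channel design: `nBio` biological replicates x 2
# temperatures x `nTech` channels for one strain, all in one run unless
# runs are given.
toyDesign <- function(strain = "CC7", nBio = 2, nTech = 2,
                      temperatures = c("control", "stress"), run = "run1") {
  g <- expand.grid(tech_rep = seq_len(nTech), bio_rep = seq_len(nBio),
                   temperature = temperatures, strain = strain,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(
    sample_id = paste(g$strain, g$temperature, paste0("b", g$bio_rep),
                      paste0("t", g$tech_rep), sep = "_"),
    assay = "protein", strain = g$strain, temperature = g$temperature,
    bio_rep = g$bio_rep, tech_rep = g$tech_rep, run = run,
    stringsAsFactors = FALSE)
}

# Build a PeptideExperiment from explicit long-format rows.
toyPe <- function(peptide_id, gene_ids, sample_id, intensity, design,
                  run = NULL, stage = "raw") {
  if (is.null(run))
    run <- design$run[match(sample_id, design$sample_id)]
  PeptideExperiment(
    data.frame(peptide_id = peptide_id, gene_ids = gene_ids, run = run,
               sample_id = sample_id, intensity = intensity,
               stringsAsFactors = FALSE),
    design, stage = stage)
}

# A small complete simulated study used by several files.
smallStudy <- function(nGenes = 120, seed = 42, ...) {
  simulateStudy(SimConfig(nGenes = nGenes, seed = seed, ...))
}

# Independent step-up implementation of the Benjamini-Hochberg adjustment,
# written directly from the definition (used as oracle).
bhBruteForce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Closed-form Welch t-test for two samples (oracle).
welchOracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(b) - mean(a)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}
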