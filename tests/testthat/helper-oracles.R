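# Independent oracles used across the suite. Each is a deliberately naive
# transcription of the underlying definition, kept separate from the package
# implementation it checks.

# literal transcription of the CCF relation
oracle_ccf <- function(vaf, purity, ploidy_cnv, ccf_cnv) {
  (vaf * (2 + (ploidy_cnv - 2) * ccf_cnv)) / purity
}

# brute-force linearity/branching: expand every mutation individually and
# classify all cross-node pairs by explicit ancestor climbing
oracle_tree_indices <- function(tree) {
  nodes <- tree$nodes
  owner <- rep(nodes$node_id, nodes$n_mutations)
  parent_of <- setNames(nodes$parent_id, nodes$node_id)
  is_ancestor <- function(a, b) { # is a a strict ancestor of b?
    cur <- parent_of[[as.character(b)]]
    while (!is.na(cur)) {
      if (cur == a) return(TRUE)
      cur <- parent_of[[as.character(cur)]]
    }
    FALSE
  }
  linear <- 0; branched <- 0
  nmut <- length(owner)
  if (nmut >= 2) {
    for (a in 1:(nmut - 1)) {
      for (b in (a + 1):nmut) {
        if (owner[a] == owner[b]) next
        if (is_ancestor(owner[a], owner[b]) || is_ancestor(owner[b], owner[a])) {
          linear <- linear + 1
        } else {
          branched <- branched + 1
        }
      }
    }
  }
  total <- linear + branched
  if (total == 0) list(linearity = 0, branching = 0)
  else list(linearity = linear / total, branching = branched / total)
}

# IC of a two-Gaussian mixture by numerical integration of the exact densities
oracle_ic_gaussian <- function(m0, m1, s0 = 1, s1 = 1, p0 = 0.5) {
  f0 <- function(y) dnorm(y, m0, s0)
  f1 <- function(y) dnorm(y, m1, s1)
  fm <- function(y) p0 * f0(y) + (1 - p0) * f1(y)
  lo <- min(m0 - 10 * s0, m1 - 10 * s1)
  hi <- max(m0 + 10 * s0, m1 + 10 * s1)
  kl <- function(fc) {
    integrate(function(y) {
      v <- fc(y)
      ifelse(v > 0, v * log2(v / fm(y)), 0)
    }, lo, hi, subdivisions = 2000L, rel.tol = 1e-10)$value
  }
  i_bits <- p0 * kl(f0) + (1 - p0) * kl(f1)
  sqrt(1 - exp(-2 * i_bits))
}

# flip-invariant gene-wise accuracy of an up/down partition against truth
partition_accuracy <- function(signature, up_truth, down_truth) {
  genes <- c(signature$up_genes, signature$down_genes)
  acc <- (sum(signature$up_genes %in% up_truth) +
            sum(signature$down_genes %in% down_truth)) / length(genes)
  max(acc, 1 - acc)
}

# tiny well-formed fixture tables written to a temp dir
write_fixture_tables <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  writeLines(c(
    "sample\tchrom\tpos\tref\talt\tgene\talt_count\tref_count",
    "S1\t7\t140753336\tA\tT\tBRAF\t30\t70",
    "S1\t1\t1000\tG\tC\tGENE1\t0\t50",
    "S1\t1\t5000\tC\tA\tGENE2\t25\t25"
  ), file.path(dir, "muts.tsv"))
  writeLines(c(
    "Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean",
    "S1\t7\t140000000\t141000000\t100\t1.0",
    "S1\t1\t1\t2000\t50\t0.0"
  ), file.path(dir, "segs.seg"))
  writeLines(c("sample\tpurity", "S1\t0.8"), file.path(dir, "purity.tsv"))
  dir
}
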