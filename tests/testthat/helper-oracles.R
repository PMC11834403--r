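# Independent oracles used across tests. These deliberately re-derive
# quantities through different code paths than the package.

# Bray-Curtis by the raw formula
oracleBrayCurtis <- function(x, y) sum(abs(x - y)) / sum(x + y)

# Spearman correlation via the rank/Pearson route, ties averaged
oracleSpearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# all permutations of 1..n, iterative construction (differs from the
# package's recursive enumerator)
oraclePermutations <- function(n) {
  perms <- list(1L)
  for (k in 2:n) {
    out <- vector("list", length(perms) * k)
    i <- 0L
    for (p in perms) for (pos in 0:(k - 1)) {
      i <- i + 1L
      out[[i]] <- append(p, k, after = pos)
    }
    perms <- out
  }
  perms
}

# projected (proximal) gradient solver for the glasso objective
#   min -logdet(Theta) + tr(S Theta) + lambda * ||offdiag(Theta)||_1
oracleGlassoObjective <- function(Theta, S, lambda) {
  -determinant(Theta, logarithm = TRUE)$modulus[1] + sum(S * Theta) +
    lambda * (sum(abs(Theta)) - sum(abs(diag(Theta))))
}

oracleGlassoPG <- function(S, lambda, maxit = 50000, tol = 1e-12) {
  Theta <- diag(1 / diag(S))
  f <- oracleGlassoObjective(Theta, S, lambda)
  t0 <- 0.1
  for (it in seq_len(maxit)) {
    G <- S - solve(Theta)
    t <- t0
    repeat {
      Z <- Theta - t * G
      off <- abs(Z) - t * lambda
      off[off < 0] <- 0
      Znew <- sign(Z) * off
      diag(Znew) <- diag(Z)
      Znew <- (Znew + t(Znew)) / 2
      ok <- !inherits(try(chol(Znew), silent = TRUE), "try-error")
      if (ok) {
        fn <- oracleGlassoObjective(Znew, S, lambda)
        if (fn <= f + 1e-14) break
      }
      t <- t / 2
      if (t < 1e-13) {
        Znew <- Theta
        fn <- f
        break
      }
    }
    conv <- abs(f - fn) < tol && it > 10
    Theta <- Znew
    f <- fn
    if (conv) break
  }
  list(Theta = Theta, objective = f)
}

# small consistent table trio on disk for reader tests
writeFixtureTables <- function(dir, nSamples = 5, nAsvs = 4,
                               mutate = identity) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(99)
  cts <- matrix(rpois(nSamples * nAsvs, 30), nSamples, nAsvs,
                dimnames = list(paste0("s", seq_len(nSamples)),
                                paste0("asv", seq_len(nAsvs))))
  counts <- data.frame(sample_id = rownames(cts), cts, check.names = FALSE)
  meta <- data.frame(sample_id = rownames(cts),
                     date = format(as.Date("2004-01-01") +
                                     30 * seq_len(nSamples), "%Y-%m-%d"),
                     depth = "surface")
  tax <- data.frame(asv_id = colnames(cts),
                    lineage = paste("Eukaryota;TSAR;Alveolata",
                                    "Dinoflagellata;Dinophyceae",
                                    "Gymnodiniales;Gymnodiniaceae",
                                    paste0("Genus", seq_len(nAsvs)),
                                    sep = ";"))
  fx <- mutate(list(counts = counts, meta = meta, tax = tax))
  paths <- c(counts = file.path(dir, "counts.tsv"),
             meta = file.path(dir, "meta.tsv"),
             tax = file.path(dir, "tax.tsv"))
  write.table(fx$counts, paths["counts"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(fx$meta, paths["meta"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(fx$tax, paths["tax"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}

# hand-built taxonomy exercising every matching rule
ruleFixtureTaxonomy <- function() {
  lin <- c(
    synd = paste0("Eukaryota;TSAR;Alveolata;Dinoflagellata;Syndiniales;",
                  "Syndiniales Group II;Dino-Group-II;Dino-Group-II_XX"),
    tripos = paste0("Eukaryota;TSAR;Alveolata;Dinoflagellata;Dinophyceae;",
                    "Gonyaulacales;Ceratiaceae;Tripos"),
    acanth = paste0("Eukaryota;TSAR;Rhizaria;Radiolaria;Acantharea;",
                    "Chaunacanthida;Acantharea Clade F;Acantharea_X"),
    phaeo = paste0("Eukaryota;Haptista;Haptophyta;Prymnesiophyceae;",
                   "Phaeocystales;Phaeocystales;Phaeocystaceae;Phaeocystis"),
    mast = paste0("Eukaryota;TSAR;Stramenopiles;Bigyra;Sagenista;MAST-3;",
                  "MAST-3E;MAST-3E_X"),
    chaeto = paste0("Eukaryota;TSAR;Stramenopiles;Gyrista;",
                    "Bacillariophyceae;Chaetocerotales;Chaetocerotaceae;",
                    "Chaetoceros"),
    dino = paste0("Eukaryota;TSAR;Alveolata;Dinoflagellata;Dinophyceae;",
                  "Dinophysiales;Dinophysiaceae;Dinophysis"),
    tele = paste0("Eukaryota;Cryptista;Cryptophyta;Cryptophyceae;",
                  "Cryptomonadales;Pyrenomonadales;Geminigeraceae;",
                  "Teleaulax"),
    stub = paste0("Eukaryota;TSAR;Alveolata;Dinoflagellata;Dinophyceae;",
                  "Dinophyceae_X;Dinophyceae_XX;Dinophyceae_XXX"))
  keys <- deriveTaxonKeys(unname(lin))
  rownames(keys) <- names(lin)
  keys
}

ruleFixtureDb <- function(dir) {
  rec <- data.frame(
    record_id = paste0("R", 1:4),
    taxon_a_key = c("group ii", "acantharea clade f", "MAST-3",
                    "Dinophysis"),
    taxon_a_rank = c("syndiniales_group", "radiolarian_class", "mast_clade",
                     "genus"),
    taxon_b_key = c("Tripos", "Phaeocystis", "Chaetoceros", "Teleaulax"),
    taxon_b_rank = "genus",
    interaction_type = c("parasitism", "symbiosis", "symbiosis",
                         "unresolved"))
  path <- file.path(dir, "rules_db.tsv")
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  parseInteractionDB(path, provenance = "rule fixture")
}
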