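# Builds the bundled synthetic interfacial pair potential and interface
# composition under inst/extdata/. The matrix is synthetic: residue-pair
# energies are drawn around group-level contact energies for the nine-group
# modified classification (hydrophobic packing, aromatic stacking, salt
# bridges, like-charge repulsion, disulfide pairing), with small
# within-group jitter. It stands in for a published interfacial statistical
# potential in examples and tests; supply a published matrix for real use.
# Deterministic: fixed seed, full-precision text output.

AA <- c("A","R","N","D","C","Q","E","G","H","I",
        "L","K","M","F","P","S","T","W","Y","V")

groups <- list(g1 = c("A","G"), g2 = c("V","M","L","I"), g3 = c("P","S","T"),
               g4 = c("F","Y","W"), g5 = "C", g6 = c("H","R"), g7 = "K",
               g8 = c("D","E"), g9 = c("N","Q"))
a2g <- integer(20); names(a2g) <- AA
for (g in seq_along(groups)) a2g[groups[[g]]] <- g

# group-level contact energies (negative = favourable)
M <- matrix(0, 9, 9)
set <- function(i, j, v) { M[i, j] <<- v; M[j, i] <<- v }
set(1, 1, -0.3); set(1, 2, -0.6); set(1, 3, -0.1); set(1, 4, -0.5)
set(1, 5, -0.3); set(1, 6,  0.0); set(1, 7,  0.1); set(1, 8,  0.0)
set(1, 9, -0.1)
set(2, 2, -1.6); set(2, 3, -0.2); set(2, 4, -1.5); set(2, 5, -0.6)
set(2, 6, -0.1); set(2, 7,  0.5); set(2, 8,  0.4); set(2, 9,  0.0)
set(3, 3, -0.2); set(3, 4, -0.3); set(3, 5, -0.1); set(3, 6, -0.2)
set(3, 7,  0.1); set(3, 8, -0.1); set(3, 9, -0.3)
set(4, 4, -1.8); set(4, 5, -0.5); set(4, 6, -0.5); set(4, 7, -0.3)
set(4, 8,  0.0); set(4, 9, -0.2)
set(5, 5, -2.2); set(5, 6, -0.2); set(5, 7,  0.1); set(5, 8,  0.0)
set(5, 9, -0.1)
set(6, 6,  0.2); set(6, 7,  0.5); set(6, 8, -1.2); set(6, 9, -0.3)
set(7, 7,  0.8); set(7, 8, -1.3); set(7, 9, -0.2)
set(8, 8,  0.6); set(8, 9, -0.4)
set(9, 9, -0.4)

set.seed(20230211)
S <- matrix(NA_real_, 20, 20, dimnames = list(AA, AA))
for (i in 1:20) for (j in i:20) {
  v <- M[a2g[AA[i]], a2g[AA[j]]] + rnorm(1, 0, 0.08)
  S[i, j] <- S[j, i] <- round(v, 4)
}

comp <- c(A = 0.07, R = 0.05, N = 0.04, D = 0.05, C = 0.02, Q = 0.04,
          E = 0.06, G = 0.07, H = 0.03, I = 0.06, L = 0.09, K = 0.06,
          M = 0.02, F = 0.04, P = 0.04, S = 0.06, T = 0.06, W = 0.02,
          Y = 0.04, V = 0.08)
stopifnot(abs(sum(comp) - 1) < 1e-12)

out <- file.path("inst", "extdata")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
write.table(data.frame(aa = AA, S, check.names = FALSE),
            file.path(out, "potential_synthetic.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(aa = names(comp), fraction = comp),
            file.path(out, "composition_synthetic.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
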