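# Independent brute-force oracles (explicit loops) for the metric formulas,
# plus small coordinate-fixture builders.

pearson_loop <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx2 <- 0; dy2 <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx2 <- dx2 + (x[i] - mx)^2
    dy2 <- dy2 + (y[i] - my)^2
  }
  num / sqrt(dx2 * dy2)
}

rmse_loop <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
  sqrt(s / length(x))
}

r2_loop <- function(pred, truth) {
  my <- sum(truth) / length(truth)
  sse <- 0; sst <- 0
  for (i in seq_along(pred)) {
    sse <- sse + (pred[i] - truth[i])^2
    sst <- sst + (truth[i] - my)^2
  }
  1 - sse / sst
}

mmd2_loop <- function(X, Y, bw) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  k <- function(a, b) exp(-bw * sum((a - b)^2))
  m <- nrow(X); n <- nrow(Y)
  s1 <- 0; s2 <- 0; s3 <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) s1 <- s1 + k(X[i, ], X[j, ])
  for (i in seq_len(n)) for (j in seq_len(n)) s2 <- s2 + k(Y[i, ], Y[j, ])
  for (i in seq_len(m)) for (j in seq_len(n)) s3 <- s3 + k(X[i, ], Y[j, ])
  s1 / m^2 + s2 / n^2 - 2 * s3 / (m * n)
}

# minimal fixed-width PDB builder for hand-placed fixtures
pdb_fixture <- function(atoms) {
  # atoms: data.frame with name, resname, chain, resno, x, y, z, element
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    name_fmt <- if (nchar(a$name) < 4) sprintf(" %-3s", a$name) else a$name
    sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, name_fmt, a$resname, a$chain, a$resno, a$x, a$y, a$z,
            1, 0, a$element)
  }, "")
  paste(c(lines, "END"), collapse = "\n")
}

atom_row <- function(name, resname, resno, x, y, z,
                     chain = "A", element = substr(name, 1, 1)) {
  data.frame(name = name, resname = resname, chain = chain, resno = resno,
             x = x, y = y, z = z, element = element,
             stringsAsFactors = FALSE)
}

# a glycine-like residue stub (backbone only) at an offset
backbone_res <- function(resname, resno, ox, oy = 0, oz = 0, chain = "A") {
  rbind(
    atom_row("N", resname, resno, ox, oy + 1.0, oz, chain),
    atom_row("CA", resname, resno, ox + 1.2, oy, oz, chain),
    atom_row("C", resname, resno, ox + 2.0, oy + 1.0, oz, chain),
    atom_row("O", resname, resno, ox + 3.0, oy + 1.2, oz, chain)
  )
}
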