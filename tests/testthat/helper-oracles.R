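# Independent brute-force oracles, written as explicit double loops so they
# share no code path with the package implementations they check.

bf_energy_maxdo <- function(xa, xb, B, C, qa, qb) {
  if (length(B) == 1) B <- matrix(B, nrow(xa), nrow(xb))
  if (length(C) == 1) C <- matrix(C, nrow(xa), nrow(xb))
  e <- 0
  for (i in seq_len(nrow(xa))) {
    for (j in seq_len(nrow(xb))) {
      r <- sqrt(sum((xa[i, ] - xb[j, ])^2))
      e <- e + B[i, j] / r^8 - C[i, j] / r^6 + qa[i] * qb[j] / (15 * r^2)
    }
  }
  e
}

bf_energy_iattract <- function(xa, xb, sigma, qa, qb) {
  if (length(sigma) == 1) sigma <- matrix(sigma, nrow(xa), nrow(xb))
  e <- 0
  for (i in seq_len(nrow(xa))) {
    for (j in seq_len(nrow(xb))) {
      r <- sqrt(sum((xa[i, ] - xb[j, ])^2))
      e <- e + (sigma[i, j] / r)^12 - (sigma[i, j] / r)^6 + qa[i] * qb[j] / (10 * r)
    }
  }
  e
}

bf_interface <- function(xa, ra, xb, rb, d) {
  ia <- ib <- integer(0)
  for (i in seq_len(nrow(xa))) {
    for (j in seq_len(nrow(xb))) {
      if (sqrt(sum((xa[i, ] - xb[j, ])^2)) < d) {
        ia <- c(ia, ra[i]); ib <- c(ib, rb[j])
      }
    }
  }
  list(a = sort(unique(ia)), b = sort(unique(ib)))
}

bf_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

bf_sociability <- function(m) {
  n <- nrow(m)
  s <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) acc <- acc + m[i, j] + m[j, i]
    s[i] <- acc / (2 * n)
  }
  s
}

bf_nii <- function(m, eps = 1e-9) {
  s <- bf_sociability(m)
  n <- nrow(m)
  iip <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    iip[i, j] <- m[i, j] / sqrt(max(abs(s[i]), eps) * max(abs(s[j]), eps))
  }
  nii <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- min(iip[i, j], iip[j, i])
    den <- (max(abs(min(iip[i, ])), eps) * max(abs(min(iip[, j])), eps) *
              max(abs(min(iip[, i])), eps) * max(abs(min(iip[j, ])), eps))^(1 / 4)
    nii[i, j] <- num / den
  }
  list(s = s, iip = iip, nii = nii)
}

bf_mwu_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# single-bead toy protein with explicit LJ scales, used by energy tests
bead_protein <- function(id, xyz, q = 0, sigma = 1, eps = 1) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  cg_protein(id, tibble::tibble(
    res_idx = seq_len(n) - 1L, role = "CA",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    q = rep_len(q, n), type = "BEAD",
    sigma = rep_len(sigma, n), eps = rep_len(eps, n)
  ))
}

# scales chosen so the derived pair coefficients are B = C = 1:
# (3/4) sigma^2 = 1 and 4 eps sigma^6 = 1
unit_bc_protein <- function(id, xyz, q = 0) {
  sigma <- sqrt(4 / 3)
  eps <- 1 / (4 * sigma^6)
  bead_protein(id, xyz, q = q, sigma = sigma, eps = eps)
}

# minimal PDB text for authored-fixture parsing tests
write_mini_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom <- function(serial, name, resid, chain, resno, x, y, z, occ = 1, alt = " ", elem = NULL) {
  if (is.null(elem)) elem <- substr(trimws(name), 1, 1)
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", name), alt, resid, chain, resno, x, y, z, occ, 0, elem)
}
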