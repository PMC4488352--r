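# Shared helpers: seeded random rigid motions, random helical curves, and a
# tiny PDB writer used to exercise the reader with hand-controlled records.

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

random_curve <- function(r_range = c(1.5, 12), p_range = c(0.5, 4),
                         t_range = c(0.3, 2.5)) {
  t <- runif(1, t_range[1], t_range[2]) * sample(c(-1, 1), 1)
  helical_curve(runif(1, r_range[1], r_range[2]),
                runif(1, p_range[1], p_range[2]),
                t, random_rotation(), runif(3, -20, 20))
}

# apply a rigid motion (Q, s) to an n x 3 point matrix
rigid <- function(xyz, Q, s) t(Q %*% t(xyz)) + matrix(s, nrow(xyz), 3,
                                                      byrow = TRUE)

# minimal fixed-column PDB ATOM line (altloc and occupancy controllable)
pdb_atom_line <- function(serial, elety, resid, chain, resno, xyz,
                          altloc = " ", occ = 1.00) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, sprintf(" %-3s", elety), altloc, resid, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, 0)
}

# a quad_fit-shaped stub with chosen parameters, for scoring tests
stub_fit <- function(r, p, t, delta) {
  structure(list(window_start = 1L,
                 curve = helical_curve(r, p, t),
                 delta = delta, corr_rmsd = delta,
                 atom_phases = t * 0:3, atom_dists = rep(delta, 4),
                 seed = list(r = r, p = p, t = t)),
            class = "quad_fit")
}
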