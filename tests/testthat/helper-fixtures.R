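# Shared fixture builders; everything is generated in code at test time.

rot_axis <- function(axis = c(0, 0, 1), theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

# minimal structure from a coordinate matrix (one atom per residue)
struct_from_xyz <- function(xyz, name = "CA", element = "C", resname = "ALA",
                            chain = "A", b = 0, hetero = FALSE) {
  n <- nrow(xyz)
  atoms <- data.frame(
    serial = seq_len(n), name = rep_len(name, n), alt = rep_len("", n),
    resname = rep_len(resname, n), chain = rep_len(chain, n),
    resseq = seq_len(n), icode = rep_len("", n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = rep_len(1, n),
    b = rep_len(b, n), element = rep_len(element, n),
    is_hetero = rep_len(hetero, n), stringsAsFactors = FALSE)
  dynimpact:::.new_structure(atoms)
}

# an ensemble with explicit frames over a toy structure's atoms
ens_from_frames <- function(structure, frames, replicate_id = 1, label = "WT") {
  a <- structure$atoms
  atab <- data.frame(chain = a$chain, resseq = a$resseq, icode = a$icode,
                     resname = a$resname, name = a$name, element = a$element,
                     stringsAsFactors = FALSE)
  xyz <- do.call(rbind, lapply(frames, function(m) as.vector(t(m))))
  new_ensemble(xyz, atab, replicate_id = replicate_id, label = label)
}

canonical_pka_fixture <- function(pka = c(4.0, 6.5, 10.4),
                                  resname = c("ASP", "HIS", "LYS"),
                                  resseq = c(10L, 20L, 30L)) {
  pka_table(data.frame(chain = "A", resseq = resseq, resname = resname,
                       pka = pka, stringsAsFactors = FALSE))
}

# small multi-metric score fixture used across classification tests
score_fixture <- function(values, layers, orientation = "higher_is_worse",
                          roles) {
  reg <- data.frame(metric = colnames(values), layer = layers,
                    orientation = orientation, stringsAsFactors = FALSE)
  score_table(values, reg, roles)
}
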