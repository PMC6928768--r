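# shared helpers for building tiny structural fixtures in code

atom_row <- function(serial, x, y, z, name = "CA", element = "C", resno = 1L,
                     resid = "ALA", occ = 1, ins = "") {
  data.frame(serial = as.integer(serial), name = name, element = element,
             x = x, y = y, z = z, occ = occ,
             is_heavy = !toupper(element) %in% c("H", "D"),
             resno = as.integer(resno), ins = ins, resid = resid,
             stringsAsFactors = FALSE)
}

one_atom_subunit <- function(label, x, y, z, resno = 1L, element = "C") {
  capsidhot:::new_subunit(label, label,
                          atom_row(1L, x, y, z, resno = resno, element = element))
}

# subunit made of several atoms, one residue per atom
bead_subunit <- function(label, xyz, resno = seq_len(nrow(xyz))) {
  at <- do.call(rbind, lapply(seq_len(nrow(xyz)), function(i) {
    atom_row(i, xyz[i, 1], xyz[i, 2], xyz[i, 3], resno = resno[i])
  }))
  capsidhot:::new_subunit(label, label, at)
}

# minimal capsid map from a table of (chain, resno, phi, psi)
map_from_points <- function(virus_id, pts, orientation_tag = "222") {
  pts$resid <- "ALA"
  structure(list(virus_id = virus_id, orientation_tag = orientation_tag,
                 points = pts[, c("chain", "resno", "resid", "phi", "psi")]),
            class = "capsid_map")
}

# small cached toy family shared by several test files (building it is ~1 s)
toy_family_cached <- local({
  fam <- NULL
  function() {
    if (is.null(fam)) fam <<- make_toy_family(toy_family_spec())
    fam
  }
})
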