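# Shared test fixtures built in code.

MJ <- mj_potential()

# a contact potential with arbitrary energies, for closed-form checks
synthetic_potential <- function(fill = 0, min_energy = NULL, id = "SYNTHETIC") {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  E <- matrix(fill, 20, 20, dimnames = list(aa, aa))
  if (!is.null(min_energy)) E["A", "A"] <- min_energy
  structure(list(source_id = id, energies = E, min_energy = min(E)),
            class = "contact_potential")
}

# build a cg_structure directly from coordinates
cg <- function(xyz, resid = NULL, id = "TEST", chain = "A", bfactors = NULL) {
  n <- nrow(xyz)
  if (is.null(resid)) resid <- rep("A", n)
  structure(list(structure_id = id, chain_id = chain,
                 resno = seq_len(n), insert = rep("", n),
                 resid = resid, xyz = xyz, bfactors = bfactors),
            class = "cg_structure")
}

# two compact 6-residue lobes joined by a long contact-free linker; with a
# potential whose backbone springs are negligible next to the tertiary
# springs the spectrum collapses and the model fragments numerically
dumbbell_structure <- function() {
  lobe <- function(cx) {
    rbind(c(cx, 0, 0), c(cx + 3.8, 0, 0), c(cx + 3.8, 3.8, 0),
          c(cx, 3.8, 0), c(cx, 0, 3.8), c(cx + 3.8, 0, 3.8))
  }
  linker <- cbind(seq(14, 46, by = 8), -10, 0)   # 8 A steps, no contacts
  cg(rbind(lobe(0), linker, lobe(50)), resid = rep("L", 6 + 5 + 6))
}

# hand-written PDB ATOM line (fixed columns)
atom_line <- function(serial, elety, alt, resname, chain, resno, icode,
                      x, y, z, occ = 1, b = 0) {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, paste0(" ", elety), alt, resname, chain, resno, icode,
          x, y, z, occ, b)
}
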