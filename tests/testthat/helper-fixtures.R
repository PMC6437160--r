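# tiny PDB builders (text fixtures constructed in code)
pdb_line <- function(serial, name, resname, resno, x, y, z,
                     element = "", altloc = " ", occ = 1.0, chain = "A",
                     rectype = "ATOM") {
  sprintf("%-6s%5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rectype, serial, name, altloc, resname, chain, resno, x, y, z,
          occ, 0, element)
}

toy_heme <- function() {
  # Fe + 4 pyrrole-like N in a plane
  lines <- c(
    pdb_line(1, "FE", "HEM", 1, 0, 0, 0, "FE", rectype = "HETATM"),
    pdb_line(2, "NA", "HEM", 1, 2.05, 0, 0, "N", rectype = "HETATM"),
    pdb_line(3, "NB", "HEM", 1, -2.05, 0, 0, "N", rectype = "HETATM"),
    pdb_line(4, "NC", "HEM", 1, 0, 2.05, 0, "N", rectype = "HETATM"),
    pdb_line(5, "ND", "HEM", 1, 0, -2.05, 0, "N", rectype = "HETATM")
  )
  paste(lines, collapse = "\n")
}
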