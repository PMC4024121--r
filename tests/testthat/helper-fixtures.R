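# Shared fixture builders: PDB ATOM lines, small traces, mutation tables.

atom_line <- function(serial, resno, x, y, z, chain = "A", res3 = "ALA",
                      atom = " CA ", alt = " ", icode = " ",
                      record = "ATOM  ", trailing = "  1.00  0.00") {
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%s",
          record, serial, atom, alt, res3, chain, resno, icode,
          x, y, z, trailing)
}

# trace with an arbitrary sequence laid on an ideal helix
seq_trace <- function(seq_str, res_seq = NULL, structure_id = "test") {
  aa <- strsplit(seq_str, "")[[1]]
  tr <- make_helix(length(aa), structure_id = structure_id)
  tr$residues$aa <- aa
  if (!is.null(res_seq)) tr$residues$res_seq <- as.integer(res_seq)
  tr
}

# mutation_counts directly from a named position->count map
counts_from_map <- function(map, n_samples = 1L) {
  collapse_counts(plant_mutations(map, n_samples = n_samples))
}

mutation_tsv <- function(rows) {
  c(paste(c("sample_id", "protein_id", "position", "ref_aa", "alt_aa",
            "mutation_class", "somatic_status"), collapse = "\t"),
    rows)
}

mut_row <- function(sample = "S1", protein = "PROT", pos = 1,
                    ref = "A", alt = "V", class = "missense",
                    status = "Confirmed somatic variant") {
  paste(sample, protein, pos, ref, alt, class, status, sep = "\t")
}

path_len <- function(D, s) sum(D[cbind(s[-length(s)], s[-1])])
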