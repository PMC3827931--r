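#' Read a PDB-format complex
#'
#' Minimal fixed-column reader for `ATOM`/`HETATM` records: only the first
#' model of a multi-model file is kept, waters are skipped, and chains are
#' classified as RNA or protein by majority vote over their residue names
#' (standard amino acids against nucleotides; modified residues fall back
#' to `X`/`N`). Chain sequences are derived from the residues actually
#' present, in residue-number order. No R PDB parser ships with the
#' supported stack, hence this purpose-built reader; it is covered by
#' round-trip tests against [write_pdb()].
#'
#' @param path PDB-format file.
#' @param complex_id identifier for the complex (default: file stem).
#' @return A `complex_record`: list with `id` and `chains`, each chain a
#'   list with `chain_id`, `kind` (`"rna"`/`"protein"`), `sequence` and an
#'   `atoms` coordinate matrix (columns x, y, z, in Angstrom; `element`
#'   row names).
#' @export
read_pdb <- function(path, complex_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  end_model <- grep("^ENDMDL", lines)
  if (length(end_model)) lines <- lines[seq_len(end_model[1] - 1L)]
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(rec) == 0L)
    stop("no ATOM/HETATM records in '", path, "'", call. = FALSE)
  resname <- trimws(substr(rec, 18, 20))
  keep <- resname != "HOH"
  rec <- rec[keep]; resname <- resname[keep]
  chain <- substr(rec, 22, 22)
  resseq <- as.integer(substr(rec, 23, 26))
  x <- as.numeric(substr(rec, 31, 38))
  y <- as.numeric(substr(rec, 39, 46))
  z <- as.numeric(substr(rec, 47, 54))
  elem <- trimws(substr(rec, 77, 78))
  if (any(!is.finite(c(x, y, z))))
    stop("non-finite coordinates in '", path, "'", call. = FALSE)
  chains <- lapply(unique(chain), function(cid) {
    idx <- which(chain == cid)
    ord <- idx[order(resseq[idx])]
    res_first <- ord[!duplicated(resseq[ord])]
    kinds <- vapply(resname[res_first], residue_kind, character(1))
    kind <- names(which.max(table(factor(kinds,
                                         c("protein", "rna", "other")))))
    if (kind == "other") return(NULL)
    letters1 <- vapply(resname[res_first], residue_letter, character(1),
                       kind = kind)
    atoms <- cbind(x = x[ord], y = y[ord], z = z[ord])
    rownames(atoms) <- elem[ord]
    list(chain_id = cid, kind = kind,
         sequence = paste(letters1, collapse = ""), atoms = atoms)
  })
  chains <- Filter(Negate(is.null), chains)
  structure(list(id = complex_id %||% sub("\\.(pdb|ent)$", "",
                                          basename(path)),
                 chains = chains),
            class = "complex_record")
}

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V", SEC = "U", ASX = "B", GLX = "Z")
NUC <- c(A = "A", C = "C", G = "G", U = "U", T = "U", I = "N",
         DA = "A", DC = "C", DG = "G", DT = "U", DU = "U")

residue_kind <- function(rn) {
  if (rn %in% names(AA3)) "protein"
  else if (rn %in% names(NUC)) "rna"
  else "other"
}

residue_letter <- function(rn, kind) {
  v <- if (kind == "protein") AA3[rn] else NUC[rn]
  if (is.na(v)) {
    if (kind == "protein") "X" else "N"
  } else unname(v)
}

#' Write a complex record in PDB format
#'
#' One pseudo-atom record per stored atom; inverse of [read_pdb()] for the
#' fields that reader consumes (chain, residue, coordinates).
#'
#' @param complex a `complex_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(complex, path) {
  stopifnot(inherits(complex, "complex_record"))
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (ch in complex$chains) {
    res <- strsplit(ch$sequence, "", fixed = TRUE)[[1]]
    n_atoms <- nrow(ch$atoms)
    # spread atoms over residues evenly (one atom per residue when equal)
    res_of_atom <- rep(seq_along(res), length.out = n_atoms)
    if (n_atoms %% length(res) == 0L)
      res_of_atom <- rep(seq_along(res), each = n_atoms / length(res))
    for (i in seq_len(n_atoms)) {
      serial <- serial + 1L
      ri <- res_of_atom[i]
      if (ch$kind == "protein") {
        rn <- names(AA3)[match(res[ri], AA3)]
        if (is.na(rn)) rn <- "UNK"
        atom_name <- " CA "
      } else {
        rn <- res[ri]
        atom_name <- " P  "
      }
      writeLines(sprintf(
        "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, atom_name, "", rn, ch$chain_id, ri, "",
        ch$atoms[i, "x"], ch$atoms[i, "y"], ch$atoms[i, "z"], 1, 0,
        if (ch$kind == "protein") "C" else "P"), con)
    }
    writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}
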