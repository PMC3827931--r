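#' Propensity scales
#'
#' A propensity scale maps every residue letter of its alphabet to a real
#' value. Scales are represented as named numeric vectors with attributes
#' `scale_name`, `source` and `alphabet` (`"rna"` or `"protein"`), so a
#' trained model can serialize the exact tables it was built with.
#'
#' @param values named numeric vector (names are residue letters).
#' @param name scale name.
#' @param alphabet `"rna"` or `"protein"`.
#' @param source free-text provenance note.
#' @return A `propensity_scale` object.
#' @export
propensity_scale <- function(values, name, alphabet = c("protein", "rna"),
                             source = "") {
  alphabet <- match.arg(alphabet)
  if (length(values) == 0L)
    stop("empty propensity scale '", name, "'", call. = FALSE)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("propensity scale values must be named by residue", call. = FALSE)
  std <- if (alphabet == "rna") RNA_ALPHABET else PROTEIN_ALPHABET
  miss <- setdiff(std, names(values))
  if (length(miss))
    stop("scale '", name, "' does not cover residue(s): ",
         paste(miss, collapse = ","), call. = FALSE)
  v <- as.numeric(values)
  names(v) <- names(values)
  if (any(!is.finite(v)))
    stop("scale '", name, "' has non-finite values", call. = FALSE)
  structure(v, scale_name = name, alphabet = alphabet, source = source,
            class = "propensity_scale")
}

#' Read a propensity scale from a two-column TSV file
#'
#' The file holds `residue` and `value` columns; `#` lines are comments and
#' conventionally name the scale and its source.
#'
#' @param path TSV file path.
#' @param name scale name (defaults to the file stem).
#' @param alphabet `"rna"` or `"protein"`.
#' @return A [propensity_scale()].
#' @export
read_scale <- function(path, name = NULL,
                       alphabet = c("protein", "rna")) {
  alphabet <- match.arg(alphabet)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("residue", "value") %in% names(df)))
    stop("scale file '", path, "' must have residue/value columns",
         call. = FALSE)
  src <- grep("^# source:", readLines(path, n = 10L), value = TRUE)
  propensity_scale(stats::setNames(df$value, df$residue),
                   name = name %||% sub("\\.tsv$", "", basename(path)),
                   alphabet = alphabet,
                   source = sub("^# source:\\s*", "", src[1] %||% ""))
}

scale_file <- function(fname) {
  system.file("extdata", "scales", fname, package = "rpiscore",
              mustWork = TRUE)
}

#' Default propensity scales and Chou-Fasman tables
#'
#' Loads the scale set shipped with the package: Grantham and Zimmerman
#' polarity (protein hydrogen bonding), Kyte-Doolittle and Bull-Breese
#' (protein Van der Waals), the Chou-Fasman helix/sheet/turn tables (protein
#' structure channel), and per-base RNA hydrogen-bonding / Van der Waals
#' contact propensities. The two RNA tables are provisional synthetic
#' stand-ins (the literature values they emulate are not printed in any
#' offline-available source); see the files under
#' `system.file("extdata", "scales", package = "rpiscore")`.
#'
#' @return A list with elements `grantham`, `zimmerman`, `kd`, `bb`,
#'   `rna_hbond`, `rna_vdw` (each a [propensity_scale()]) and `chou_fasman`
#'   (a list of three scales keyed `H`, `E`, `C`).
#' @export
default_scales <- function() {
  cf <- utils::read.delim(scale_file("chou_fasman.tsv"), comment.char = "#",
                          stringsAsFactors = FALSE)
  cf_scale <- function(col, nm)
    propensity_scale(stats::setNames(cf[[col]], cf$residue),
                     name = paste0("chou_fasman_", nm), alphabet = "protein",
                     source = "Chou & Fasman (1978)")
  list(
    grantham  = read_scale(scale_file("grantham.tsv"), "grantham"),
    zimmerman = read_scale(scale_file("zimmerman.tsv"), "zimmerman"),
    kd        = read_scale(scale_file("kyte_doolittle.tsv"), "kyte_doolittle"),
    bb        = read_scale(scale_file("bull_breese.tsv"), "bull_breese"),
    rna_hbond = read_scale(scale_file("rna_hbond_synthetic.tsv"),
                           "rna_hbond", alphabet = "rna"),
    rna_vdw   = read_scale(scale_file("rna_vdw_synthetic.tsv"),
                           "rna_vdw", alphabet = "rna"),
    chou_fasman = list(H = cf_scale("helix", "helix"),
                       E = cf_scale("sheet", "sheet"),
                       C = cf_scale("turn", "turn"))
  )
}

# Extend a scale with ambiguity letters resolved to the arithmetic mean of
# their compatible residues (B over D/N, Z over E/Q, X and U over all 20;
# RNA N over A/C/G/U). Deterministic and unbiased.
resolve_ambiguity <- function(scale) {
  amb <- if (attr(scale, "alphabet") == "rna") RNA_AMBIGUITY
         else PROTEIN_AMBIGUITY
  v <- unclass(scale)
  for (letter in names(amb)) {
    if (!letter %in% names(v))
      v[letter] <- mean(v[amb[[letter]]])
  }
  v
}
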