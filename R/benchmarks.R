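## Self-contained synthetic benchmark targets used by the worked examples
## and validation experiments.

#' Synthetic benchmark targets
#'
#' Returns the definition of a built-in synthetic target: sequence,
#' dot-bracket structure and a fragment-library composition able to model
#' it.
#'
#' * `"three_stem"`: a 38-nt three-way junction — one outer stem plus two
#'   hairpin stems joined by a `junction:3:2-2-2` loop.
#' * `"two_junction"`: a 60-nt fold with two cascaded three-way junctions
#'   and three hairpins.
#'
#' @param name target name.
#' @param n_fragments fragments generated per signature (default 10).
#' @return list with `sequence`, `structure` and `library_config`
#'   (named counts for [generate_synthetic_library()]).
#' @export
benchmark_target <- function(name = c("three_stem", "two_junction"),
                             n_fragments = 10) {
  name <- match.arg(name)
  if (name == "three_stem") {
    list(
      sequence  = "GGGGAAGGGGAAAACCCCAAGGGGAAAACCCCAACCCC",
      structure = "((((..((((....))))..((((....))))..))))",
      library_config = setNames(rep(n_fragments, 3),
                                c("stem:4", "hairpin:4", "junction:3:2-2-2")))
  } else {
    list(
      sequence  = "GGGGAAGGGGAAAACCCCAAGGGGAAGGGAAAACCCAAGGGAAAACCCAACCCCAACCCC",
      structure = "((((..((((....))))..((((..(((....)))..(((....)))..))))..))))",
      library_config = setNames(rep(n_fragments, 4),
                                c("stem:4", "stem:3", "hairpin:4",
                                  "junction:3:2-2-2")))
  }
}

#' Coarse RMSD between two models after optimal superposition
#'
#' Superposes the second model's C4' trace onto the first by the Kabsch
#' algorithm and returns the C4' RMSD.
#'
#' @param a,b `rna_model` objects over the same number of residues.
#' @return RMSD in Angstrom.
#' @export
model_rmsd <- function(a, b) {
  if (length(a$seq) != length(b$seq)) stop("models differ in length")
  ok <- !is.na(a$C4p[, 1]) & !is.na(b$C4p[, 1])
  superpose(b$C4p[ok, , drop = FALSE], a$C4p[ok, , drop = FALSE])$rmsd
}
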