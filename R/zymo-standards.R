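#' @include AllClasses.R
NULL

.loadStandard <- function(file) {
    path <- system.file("extdata", file, package = "bsinc")
    if (!nzchar(path))  # during in-source development
        path <- file.path("inst", "extdata", file)
    std <- .readTsv(path)
    copies <- std$gdna_percent / std$genome_size_mbp
    std$rel_copies <- copies / sum(copies)
    std
}

#' Bundled mock-community DNA standard compositions
#'
#' Theoretical compositions of two commercial mock-community standards used
#' as spike-in controls and complex mock samples: a 10-member log-distributed
#' microbial DNA standard (abundances spanning about six decades of genomic
#' DNA, dominated by *Listeria monocytogenes*) and a 21-member gut microbiome
#' standard with relatively even abundances. Tables carry the manufacturer's
#' theoretical genomic-DNA percentages and genome sizes; `rel_copies` is the
#' derived genome-copy relative abundance (`gdna_percent / genome_size`,
#' normalized), the quantity the spike-in truth tables and Simpson summaries
#' are defined on. The Simpson dominance of the two standards is about 0.9
#' (log) and 0.11 (gut).
#'
#' @return data.frame: `organism`, `abbrev`, `gdna_percent`,
#'   `genome_size_mbp`, `rel_copies`.
#' @seealso [simpsonDominance()]
#' @examples
#' simpsonDominance(setNames(zymoLogStandard()$rel_copies,
#'                           zymoLogStandard()$abbrev))
#' @export
zymoLogStandard <- function() .loadStandard("zymo_log_dna_composition.tsv")

#' @rdname zymoLogStandard
#' @export
zymoGutStandard <- function() .loadStandard("zymo_gut_composition.tsv")
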