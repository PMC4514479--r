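## Antisense DNA probe sets used in the pulldown design: 15 probes against
## the target lncRNA, split into odd/even pools by 1-based index parity,
## and the LacZ control probe set (7 sequences are published; the stated
## count of eight is a known inconsistency and only the printed seven are
## shipped).
.PROBES_TARGET <- c(
  "ATGGAAACCAGAATTCGCGC",
  "CGAGTAACAAACTGCCGCAG",
  "AAAACCAACTCTTCACCAGG",
  "CATGGAGAGACCAAACTGCT",
  "TGAGCAAAGGGAAGCTGTCA",
  "ACATAGTTCTAGCAGATGCT",
  "AGGCCAGAAAATGTCCAGAC",
  "AACACATCCCTTTATCTTCT",
  "ATCCACAGCAAAAAGGCTGG",
  "TCTTCAGCAATGGATGGTGA",
  "TAGTGTCAGGTGTGTTTGAC",
  "GTGGAGAAGGGTGAGAAGAC",
  "TAGGTATTTTTCAGTTCTGT",
  "AATGCTAAAAGCAGGGGATC",
  "AGTTTAGAGAAGTATGCCAT"
)

.PROBES_LACZ <- c(
  "ATTAAGTTGGGTAACGCCAG",
  "AATAATTCGCGTCTGGCCTT",
  "ATCTTCCAGATAACTGCCGT",
  "AACTGTTACCCGTAGGTAGT",
  "ACCATTTTCAATCCGCACCT",
  "TGGTTCGGATAATGCGAACA",
  "ATTTGATCCAGCGATACAGC"
)

#' Load a packaged probe set
#'
#' Returns the pulldown probe sequences: the 15 antisense probes targeting
#' the target lncRNA (assigned to odd/even pools by 1-based index parity)
#' or the 7 LacZ control probes.
#'
#' @param name `"target"` or `"lacz"`.
#' @return Tibble with columns `index`, `sequence`, `pool` (`"odd"`,
#'   `"even"`, or `"control"` for the LacZ set) and `set`.
#' @export
#' @examples
#' load_probes("target")
load_probes <- function(name = c("target", "lacz")) {
  name <- match.arg(name)
  seqs <- switch(name, target = .PROBES_TARGET, lacz = .PROBES_LACZ)
  idx <- seq_along(seqs)
  pool <- if (name == "target") {
    ifelse(idx %% 2 == 1, "odd", "even")
  } else "control"
  tibble(index = idx, sequence = seqs, pool = pool, set = name)
}

#' Export a probe set as FASTA
#'
#' @param name `"target"` or `"lacz"`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
export_probes_fasta <- function(name = c("target", "lacz"), path) {
  name <- match.arg(name)
  p <- load_probes(name)
  write_fasta(setNames(p$sequence,
                       sprintf("%s_probe_%d|%s", p$set, p$index, p$pool)),
              path)
}
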