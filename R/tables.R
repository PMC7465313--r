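## Published apple MYB10 design tables, shipped as plain data so the guide
## geometry, cut-site and amplicon arithmetic can be recomputed from the
## printed coordinates alone (no apple genome required).

#' Published crRNA guides flanking the apple MYB10 red-flesh locus
#'
#' The four guides used to excise the Type 1 red-flesh minisatellite region
#' upstream of *MYB10* on apple chromosome 9: name, 20-nt protospacer plus
#' NGG PAM (5'-3' on the guide strand), published specificity and on-target
#' activity scores, and 1-based inclusive genomic coordinates. Strand is
#' stored explicitly (the third guide targets the reverse strand); the
#' activity scores are carried as data only, this package does not recompute
#' them.
#'
#' @return A guide `data.frame` (columns `name`, `protospacer`, `pam`,
#'   `on_target_activity`, `contig`, `start`, `end`, `strand`).
#' @examples
#' on_target_window(myb10_guides(), mode = "cut_span")$length  # 9177
#' @export
myb10_guides <- function() {
  seqs <- c(crRNA_RF_1_F = "GTCATATCTAAGGACCCGCGTGG",
            crRNA_RF_2_F = "TCTGTACTCCGTCTGTCGGTCGG",
            crRNA_RF_3_R = "AGAAGACTGTCAATCCCGAGTGG",
            crRNA_RF_4_F = "TGTCTGGAAAGTTTCTAACGCGG")
  data.frame(
    name = names(seqs),
    protospacer = substr(unname(seqs), 1, 20),
    pam = substr(unname(seqs), 21, 23),
    on_target_activity = c(76.3, 77.9, 79.6, 70.8),
    contig = "Chr09",
    start = c(35542701L, 35542848L, 35550689L, 35551878L),
    end = c(35542723L, 35542870L, 35550711L, 35551900L),
    strand = c("+", "+", "-", "+"),
    stringsAsFactors = FALSE)
}

#' Published primer pairs for the MYB10 guide cleavage test
#'
#' Primer sequences, melting temperatures, GC percentages and 1-based
#' chromosome-9 coordinates for the three amplicons used to verify Cas9
#' cleavage of each guide in vitro.
#'
#' @return `data.frame` with columns `name`, `crRNA`, `sequence`, `tm`,
#'   `gc_percent`, `start`, `end`, `direction` (`F`/`R`).
#' @seealso [predict_amplicon_fragments()]
#' @export
myb10_primers <- function() {
  data.frame(
    name = c("Chr9_35542587_F", "Chr9_35542966_R", "Chr9_35550584_F",
             "Chr9_35550962_R", "Chr9_35551563_F", "Chr9_35552158_R"),
    crRNA = c("crRNA_RF_1, crRNA_RF_2", "crRNA_RF_1, crRNA_RF_2",
              "crRNA_RF_3", "crRNA_RF_3", "crRNA_RF_4", "crRNA_RF_4"),
    sequence = c("AACAAGATGATGACGACGTG", "GATGCACGAACTGATACTGT",
                 "CCCTGTATGCGAAAGACAAT", "AAAAGACCACATGCATGCTG",
                 "TGATTGAATGTCTCCACCA", "CACATGTGAGAGAGATTTGC"),
    tm = c(56.2, 55.6, 55.8, 57.3, 53.6, 54.4),
    gc_percent = c(45, 45, 45, 45, 42.1, 45),
    start = c(35542587L, 35542947L, 35550584L, 35550943L, 35551563L, 35552158L),
    end = c(35542606L, 35542966L, 35550603L, 35550962L, 35551581L, 35552177L),
    direction = c("F", "R", "F", "R", "F", "R"),
    stringsAsFactors = FALSE)
}
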