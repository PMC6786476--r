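#' Canonical plastid gene inventory
#'
#' Gene symbols of a photosynthetic Podocarpaceae-like plastome: 82
#' protein-coding genes, 32 tRNAs and 4 rRNAs. Used by the synthetic
#' reference generator and as the default reference gene set.
#'
#' @format Character vectors of gene symbols.
#' @name gene_inventory
NULL

#' @rdname gene_inventory
#' @export
PLASTID_PROTEIN_GENES <- c(
  "atpA", "atpB", "atpE", "atpF", "atpH", "atpI",
  "ndhA", "ndhB", "ndhC", "ndhD", "ndhE", "ndhF", "ndhG", "ndhH", "ndhI",
  "ndhJ", "ndhK",
  "petA", "petB", "petD", "petG", "petL", "petN",
  "psaA", "psaB", "psaC", "psaI", "psaJ",
  "psbA", "psbB", "psbC", "psbD", "psbE", "psbF", "psbH", "psbI", "psbJ",
  "psbK", "psbL", "psbM", "psbN", "psbT", "psbZ",
  "rbcL",
  "rpl2", "rpl14", "rpl16", "rpl20", "rpl22", "rpl23", "rpl32", "rpl33",
  "rpl36",
  "rps2", "rps3", "rps4", "rps7", "rps8", "rps11", "rps12", "rps14",
  "rps15", "rps16", "rps18", "rps19",
  "rpoA", "rpoB", "rpoC1", "rpoC2",
  "matK", "ccsA", "cemA", "clpP", "accD", "infA",
  "ycf1", "ycf2", "ycf3", "ycf4",
  "chlB", "chlL", "chlN"
)

#' @rdname gene_inventory
#' @export
PLASTID_TRNA_GENES <- c(
  "trnA-UGC", "trnC-GCA", "trnD-GUC", "trnE-UUC", "trnF-GAA", "trnfM-CAU",
  "trnG-GCC", "trnG-UCC", "trnH-GUG", "trnI-CAU", "trnI-GAU", "trnK-UUU",
  "trnL-CAA", "trnL-UAA", "trnL-UAG", "trnM-CAU", "trnN-GUU", "trnP-GGG",
  "trnP-UGG", "trnQ-UUG", "trnR-ACG", "trnR-CCG", "trnR-UCU", "trnS-GCU",
  "trnS-GGA", "trnS-UGA", "trnT-GGU", "trnT-UGU", "trnV-GAC", "trnV-UAC",
  "trnW-CCA", "trnY-GUA"
)

#' @rdname gene_inventory
#' @export
PLASTID_RRNA_GENES <- c("rrn16", "rrn23", "rrn4.5", "rrn5")

#' Gene partition of the default heterotroph-like scenario
#'
#' The default degraded plastome retains `HETEROTROPH_INTACT_PROTEINS`
#' (three ATP synthase subunits plus the housekeeping complement),
#' pseudogenizes `HETEROTROPH_PSEUDOGENES` (photosynthesis-related genes
#' including the light-independent chlorophyll biosynthesis trio), and
#' deletes `HETEROTROPH_DELETED_PROTEINS`;
#' `HETEROTROPH_INSERT_FRAGMENT_GENES` are deleted genes whose fragments
#' persist in other genomic compartments.
#'
#' @format Character vectors of gene symbols.
#' @name heterotroph_gene_sets
NULL

#' @rdname heterotroph_gene_sets
#' @export
HETEROTROPH_INTACT_PROTEINS <- c(
  "atpA", "atpB", "atpE",
  "rpl2", "rpl14", "rpl16", "rpl20", "rpl22", "rpl23", "rpl32", "rpl33",
  "rpl36",
  "rps2", "rps3", "rps4", "rps7", "rps8", "rps11", "rps12", "rps14",
  "rps15", "rps16", "rps18", "rps19",
  "rpoA", "rpoB", "rpoC1", "rpoC2",
  "matK", "ccsA", "cemA", "clpP", "accD"
)

#' @rdname heterotroph_gene_sets
#' @export
HETEROTROPH_PSEUDOGENES <- c(
  "chlB", "chlL", "chlN",
  "atpF", "atpH", "atpI",
  "ndhA", "ndhC", "ndhF", "ndhG", "ndhH",
  "petA", "petD", "petG",
  "psaC", "psaI",
  "psbA", "psbC", "psbD",
  "ycf3", "ycf4"
)

#' @rdname heterotroph_gene_sets
#' @export
HETEROTROPH_DELETED_PROTEINS <- setdiff(
  PLASTID_PROTEIN_GENES,
  c(HETEROTROPH_INTACT_PROTEINS, HETEROTROPH_PSEUDOGENES)
)

#' @rdname heterotroph_gene_sets
#' @export
HETEROTROPH_INSERT_FRAGMENT_GENES <- c(
  "ndhB", "ndhD", "ndhE", "ndhK", "petB", "psaA", "psaB", "psbB"
)
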