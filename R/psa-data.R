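#' Published percent-identity table for PsaA and PsaB
#'
#' The percent identity of the Photosystem I core subunits compared between
#' species pairs spanning roughly 100 Ma to 3 Ga of divergence, together
#' with fossil-informed divergence ages where available. Within-subunit
#' comparisons (`A-vs-A`, `B-vs-B`) track divergence between species;
#' between-subunit comparisons (`A-vs-B`, within one genome) track
#' divergence since the ancestral gene duplication. Land-plant pair ages
#' are midpoints of published fossil windows; the deepest two pairs carry
#' only broad age windows, recorded here as `age_min_ma`/`age_max_ma`.
#'
#' @return An identity tibble (see [identity_table()] for the schema).
#' @export
psa_identity_table <- function() {
  plant <- tibble::tribble(
    ~pair_label,                                        ~divergence_age_ma, ~a_vs_a, ~b_vs_b,
    "Arabidopsis thaliana vs Populus trichocarpa",      104.6,  98.6, 98.2,
    "Chloranthus spicatus vs Liriodendron tulipifera",  173.2,  99.2, 99.1,
    "A. thaliana vs C. spicatus",                       186.2,  96.9, 97.6,
    "A. thaliana vs Illicium oligandrum",               186.2,  96.6, 97.5,
    "A. thaliana vs Nymphaea alba",                     186.2,  97.3, 97.1,
    "A. thaliana vs Amborella trichopoda",              186.2,  96.6, 96.4,
    "Welwitschia mirabilis vs Pinus thunbergii",        215.65, 92.1, 93.1,
    "W. mirabilis vs Ginkgo biloba",                    236.75, 92.8, 94.0,
    "W. mirabilis vs Cycas taitungensis",               336.5,  92.4, 94.5,
    "A. thaliana vs Psilotum nudum",                    421.1,  91.0, 91.1,
    "A. thaliana vs Anthoceros formosae",               731.2,  91.4, 91.4,
    "A. thaliana vs Physcomitrella patens",             731.2,  92.4, 92.5,
    "A. thaliana vs Marchantia polymorpha",             745.5,  92.5, 92.5
  )
  deep <- tibble::tribble(
    ~pair_label,                                ~age_min_ma, ~age_max_ma, ~a_vs_a, ~b_vs_b,
    "A. thaliana vs Cyanidioschyzon merolae",   1100, 1800, 82.2, 80.9,
    "A. thaliana vs Gloeobacter kilaueensis",   2000, 3000, 66.5, 72.8
  )
  within <- dplyr::bind_rows(
    dplyr::mutate(plant, age_min_ma = NA_real_, age_max_ma = NA_real_),
    dplyr::mutate(deep, divergence_age_ma = NA_real_)
  )
  within <- tidyr::pivot_longer(
    within,
    cols = c("a_vs_a", "b_vs_b"),
    names_to = "subunit", values_to = "identity_pct"
  )
  within$subunit <- dplyr::recode(within$subunit,
                                  a_vs_a = "A-vs-A", b_vs_b = "B-vs-B")
  paralog <- tibble::tibble(
    pair_label = c("Arabidopsis thaliana", "Marchantia polymorpha",
                   "Cyanidioschyzon merolae", "Gloeobacter kilaueensis"),
    subunit = "A-vs-B",
    identity_pct = c(42.4, 42.3, 42.3, 43.3),
    divergence_age_ma = NA_real_,
    age_min_ma = NA_real_,
    age_max_ma = NA_real_
  )
  out <- dplyr::bind_rows(within, paralog)
  out[, c("pair_label", "subunit", "identity_pct", "divergence_age_ma",
          "age_min_ma", "age_max_ma")]
}

#' Fossil calibration points for the Photosystem I dating analysis
#'
#' Nine calibration nodes, from the Arabidopsis--Populus split (82--127 Ma)
#' to the most recent common ancestor of Cyanobacteria. The first three
#' carry both minimum and maximum bounds; the rest carry minimum bounds
#' only. The age of the cyanobacterial MRCA (node label `cyanobacteria`) is
#' a modelling choice: no bound, a 2450 Ma minimum (around the Great
#' Oxidation Event), or a 3000 Ma minimum.
#'
#' @param cyanobacteria_min_ma Minimum age for the cyanobacterial MRCA in
#'   Ma, or `NA` to leave that node uncalibrated.
#' @return A calibration tibble with columns `node_label`, `event`,
#'   `min_ma`, `max_ma`.
#' @export
psa_calibrations <- function(cyanobacteria_min_ma = 2450) {
  cal <- tibble::tribble(
    ~node_label,            ~event,                              ~min_ma, ~max_ma,
    "arabidopsis_populus",  "Arabidopsis-Populus divergence",    82,      127,
    "angiosperms",          "Angiosperms",                       124,     248,
    "gymnosperms",          "Gymnosperms",                       306,     366,
    "land_plants",          "Land plants",                       475,     NA,
    "diatoms",              "Diatoms",                           190,     NA,
    "florideae",            "Florideae",                         600,     NA,
    "photosynthetic_euks",  "MRCA of photosynthetic eukaryotes", 1600,    NA,
    "heterocystous_cyano",  "Heterocystous Cyanobacteria",       1600,    NA,
    "cyanobacteria",        "MRCA of Cyanobacteria",             NA,      NA
  )
  cal$min_ma[cal$node_label == "cyanobacteria"] <- cyanobacteria_min_ma
  if (is.na(cyanobacteria_min_ma)) {
    cal <- cal[cal$node_label != "cyanobacteria", ]
  }
  cal
}
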