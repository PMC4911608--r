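# The published query test of 51 unknown insect transcriptomes against the
# hexapod code database, embedded verbatim: species label, printed result
# (the clade the query was assigned to), generated barcode observed from the
# transcriptome, designed barcode of the true terminal category, and printed
# category. Printed quirks are preserved exactly: the label "Coleopterodea",
# the hyphen-less "False negative" of the Anoplophora row, the trailing " *"
# marking printed complete matches, and the anomalous single-character id
# token "X_A_" in the Thaumetopoea row (normalized by the parser).
table1_rows <- function() {
  r <- list(
    c("Pantala flavescens fabricius", "Pterygota",
      "T_00_I_02_X_03_E_06_R_08_X_09_X_0B_",
      "T_00_I_02_G_03_E_06_R_08_S_09_C_0B_", "False-negative"),
    c("Ischnura elegans", "Odonata",
      "X_00_I_02_X_03_E_06_R_08_X_09_C_0B_",
      "T_00_I_02_G_03_E_06_R_08_S_09_C_0B_", "Positive"),
    c("Isonychia kiangsinensis", "Ephemeroptera",
      "T_00_I_02_X_03_X_06_R_08_X_09_Q_0A_",
      "T_00_I_02_G_03_E_06_R_08_S_09_Q_0A_", "Positive"),
    c("Ephemera sp.", "Ephemeroptera",
      "T_00_I_02_X_03_E_06_R_08_S_09_Q_0A_",
      "T_00_I_02_G_03_E_06_R_08_S_09_Q_0A_", "Positive"),
    c("Eparchus insignis", "Dermaptera",
      "X_00_I_02_?_03_E_06_R_08_X_0C_Q_0D_H_0E_F_0F_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_Q_0D_H_0E_F_0F_", "Positive"),
    c("Flavoperla sp.", "Plecoptera",
      "X_00_I_02_X_03_?_06_R_08_X_0C_Q_0D_S_0G_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_Q_0D_S_0G_", "Positive"),
    c("Chondracris rosea", "Orthoptera",
      "T_00_I_02_X_03_E_06_R_08_S_0C_Q_0D_M_0H_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_Q_0D_M_0H_", "Positive"),
    c("Gryllotalpa unispina", "Orthoptera",
      "?_00_I_02_X_03_E_06_R_08_S_0C_Q_0D_M_0H_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_Q_0D_M_0H_", "Positive"),
    c("Hymenopus coronatus", "Mantodea",
      "X_00_I_02_X_03_E_06_R_08_S_0C_Q_0D_M_0I_H_0P_C_0R_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_Q_0D_M_0I_H_0P_C_0R_", "Positive"),
    c("Phraortes sp.", "Phasmida",
      "T_00_I_02_X_03_X_06_R_08_X_0C_Q_0D_M_0I_X_0J_L_0M_V_0O_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_Q_0D_M_0I_K_0J_L_0M_V_0O_", "Positive"),
    c("Coptotermes formosanus", "Blattodea",
      "T_00_I_02_X_03_E_06_R_08_S_0C_Q_0D_M_0I_H_0P_T_0S_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_Q_0D_M_0I_H_0P_T_0S_", "Positive"),
    c("Eupolyphaga sinensis", "Blattodea",
      "T_00_I_02_X_03_E_06_R_08_S_0C_Q_0D_M_0I_X_0P_T_0S_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_Q_0D_M_0I_H_0P_T_0S_", "Positive"),
    c("Periplaneta Americana", "Blattodea",
      "T_00_I_02_X_03_E_06_R_08_X_0C_Q_0D_M_0I_X_0P_T_0S_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_Q_0D_M_0I_H_0P_T_0S_", "Positive"),
    c("Pedetontus sp.", "Archaeognatha",
      "T_00_I_02_X_03_N_05_",
      "T_00_I_02_G_03_N_05_", "Positive"),
    c("Lepisma sp.", "Zygentoma",
      "T_00_I_02_X_03_E_06_T_07_",
      "T_00_I_02_G_03_E_06_T_07_", "Positive"),
    c("Anoplophora glabripennis", "Coleopterodea",
      "T_00_I_02_X_03_?_06_R_08_S_0C_X_0V_N_0X_N_0Z_R_10_H_16_X_18_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_R_10_H_16_K_18_",
      "False negative"),
    c("Antheraea assama", "Lepidoptera",
      "T_00_I_02_G_03_X_06_R_08_S_0C_X_0V_N_0X_N_0Z_N_19_L_1A_E_1C_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_L_1A_E_1C_", "Positive"),
    c("Anthonomus grandis", "Coleoptera",
      "?_00_I_02_X_03_E_06_R_08_X_0C_X_0V_N_0X_X_0Z_R_10_H_16_K_18_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_R_10_H_16_K_18_", "Positive"),
    c("Bactrocera dorsalis", "Diptera",
      "?_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_A_1D_Y_1H_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_A_1D_Y_1H_", "Positive"),
    c("Belgica antarctica", "Diptera",
      "T_00_I_02_?_03_E_06_R_08_S_0C_I_0V_?_0X_N_0Z_N_19_A_1D_Y_1H_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_A_1D_Y_1H_", "Positive"),
    c("Brassicogethes aeneus", "Coleoptera",
      "T_00_I_02_G_03_E_06_R_08_S_0C_X_0V_N_0X_N_0Z_R_10_X_16_K_18_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_R_10_H_16_K_18_", "Positive"),
    c("Chrysopa pallens", "Neuroptera",
      "T_00_I_02_G_03_E_06_R_08_S_0C_X_0V_N_0X_N_0Z_R_10_M_11_X_13_C_15_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_R_10_M_11_M_13_C_15_",
      "Positive"),
    c("Colaphellus bowringi", "Coleoptera",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_R_10_H_16_K_18_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_R_10_H_16_K_18_", "Positive"),
    c("Corydalinae sp.", "Megaloptera",
      "T_00_I_02_X_03_?_06_R_08_X_0C_X_0V_X_0X_N_0Z_R_10_X_11_X_13_R_14_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_R_10_M_11_M_13_R_14_",
      "Positive"),
    c("Crioscolia alcione", "Hymenoptera",
      "T_00_I_02_G_03_E_06_R_08_S_0C_X_0V_N_0X_L_0Y_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_L_0Y_", "Positive"),
    c("Culicoides sp.", "Diptera",
      "T_00_I_02_G_03_E_06_R_08_?_0C_I_0V_N_0X_N_0Z_N_19_A_1D_Y_1H_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_A_1D_Y_1H_", "Positive"),
    c("Dastarcus helophoroides", "Coleoptera",
      "T_00_I_02_X_03_E_06_R_08_S_0C_X_0V_N_0X_N_0Z_R_10_H_16_K_18_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_R_10_H_16_K_18_", "Positive"),
    c("Delia antiqua", "Diptera",
      "T_00_I_02_?_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_A_1D_Y_1H_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_A_1D_Y_1H_", "Positive"),
    c("Fopius arisanus", "Hymenoptera",
      "T_00_X_02_G_03_E_06_?_08_X_0C_I_0V_N_0X_L_0Y_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_L_0Y_", "Positive"),
    c("Hypothenemus hampei", "Coleoptera",
      "T_00_I_02_?_03_E_06_?_08_?_0C_?_0V_N_0X_?_0Z_R_10_H_16_K_18_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_R_10_H_16_K_18_", "Positive"),
    c("Ips typographus", "Coleoptera",
      "T_00_X_02_?_03_?_06_R_08_?_0C_X_0V_?_0X_X_0Z_R_10_X_16_K_18_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_R_10_H_16_K_18_", "Positive"),
    c("Lymantria dispar", "Lepidoptera",
      "T_00_I_02_?_03_X_06_R_08_X_0C_X_0V_N_0X_X_0Z_N_19_L_1A_E_1C_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_L_1A_E_1C_", "Positive"),
    c("Musca domestica", "Diptera",
      "T_00_I_02_G_03_E_06_R_08_S_0C_X_0V_X_0X_N_0Z_N_19_A_1D_Y_1H_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_A_1D_Y_1H_", "Positive"),
    c("Nevrorthus apatelios", "Neuroptera",
      "?_00_?_02_?_03_X_06_?_08_?_0C_X_0V_?_0X_?_0Z_R_10_?_11_X_13_C_15_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_R_10_M_11_M_13_C_15_",
      "Positive"),
    c("Nicrophorus vespilloides", "Coleoptera",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_R_10_H_16_K_18_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_R_10_H_16_K_18_",
      "Positive *"),
    c("Oropsylla silantiewi", "Siphonaptera",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_A_1D_G_1E_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_A_1D_G_1E_",
      "Positive *"),
    c("Osmia cornuta", "Hymenoptera",
      "T_00_I_02_G_03_E_06_R_08_X_0C_X_0V_N_0X_L_0Y_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_L_0Y_", "Positive"),
    c("Polistes metricus", "Hymenoptera",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_X_0X_L_0Y_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_L_0Y_", "Positive"),
    c("Raphidia ariadne", "Raphidioptera",
      "T_00_X_02_G_03_?_06_R_08_X_0C_X_0V_?_0X_X_0Z_?_10_X_11_N_12_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_R_10_M_11_N_12_",
      "Positive"),
    c("Rhodinia newara", "Lepidoptera",
      "T_00_I_02_G_03_E_06_R_08_S_0C_X_0V_N_0X_N_0Z_N_19_L_1A_E_1C_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_L_1A_E_1C_", "Positive"),
    c("Samia ricini", "Lepidoptera",
      "T_00_I_02_G_03_X_06_R_08_S_0C_X_0V_N_0X_X_0Z_N_19_L_1A_E_1C_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_L_1A_E_1C_", "Positive"),
    c("Sitodiplosis mosellana", "Diptera",
      "?_00_I_02_G_03_?_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_?_1D_Y_1H_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_A_1D_Y_1H_", "Positive"),
    c("Stomoxys calcitrans", "Diptera",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_A_1D_Y_1H_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_A_1D_Y_1H_",
      "Positive *"),
    c("Telchin licus", "Lepidoptera",
      "?_00_?_02_G_03_X_06_R_08_X_0C_X_0V_?_0X_?_0Z_N_19_?_1A_E_1C_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_L_1A_E_1C_", "Positive"),
    c("Telenomus podisi", "Hymenoptera",
      "T_00_X_02_?_03_E_06_R_08_S_0C_X_0V_N_0X_L_0Y_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_L_0Y_", "Positive"),
    c("Teleopsis whitei", "Diptera",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_A_1D_Y_1H_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_A_1D_Y_1H_",
      "Positive *"),
    c("Tetramorium bicarinatum", "Hymenoptera",
      "T_00_I_02_?_03_E_06_R_08_S_0C_X_0V_N_0X_L_0Y_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_L_0Y_", "Positive"),
    c("Thaumetopoea pityocampa", "Lepidoptera",
      "?_00_?_02_?_03_?_06_R_08_?_0C_?_0V_X_0X_?_0Z_N_19_X_A_E_1C_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_L_1A_E_1C_", "Positive"),
    c("Themira biloba", "Diptera",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_A_1D_Y_1H_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_A_1D_Y_1H_",
      "Positive *"),
    c("Xyela alpigena", "Holometabola",
      "?_00_?_02_?_03_X_06_X_08_?_0C_X_0V_N_0X_?_0Y_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_L_0Y_", "False-negative"),
    c("Yponomeuta evonymellus", "Lepidoptera",
      "X_00_I_02_X_03_X_06_R_08_S_0C_X_0V_N_0X_X_0Z_N_19_L_1A_E_1C_",
      "T_00_I_02_G_03_E_06_R_08_S_0C_I_0V_N_0X_N_0Z_N_19_L_1A_E_1C_", "Positive")
  )
  m <- do.call(rbind, r)
  tibble::tibble(species = m[, 1], printed_result = m[, 2],
                 generated = m[, 3], designed = m[, 4],
                 printed_category = m[, 5])
}

# Internal clade labels the source study names for IDs that are not
# terminal categories; all other internal IDs get generic labels.
internal_clade_labels <- function() {
  c("02" = "Insecta", "03" = "Ectognatha", "08" = "Pterygota",
    "0D" = "Polyneoptera", "0X" = "Holometabola", "16" = "Coleopterodea")
}

#' The embedded 51-transcriptome query-test fixture
#'
#' The published query test embedded verbatim: per row the species, the
#' printed assignment result, the generated (observed) barcode, the
#' designed barcode of the true terminal category, and the printed
#' category. Normalized helper columns are added: `truth` (terminal
#' category name implied by the designed barcode), `category_norm`
#' (`positive` / `false_negative`) and `printed_complete_match` (the
#' trailing `*` marker).
#'
#' @return a 51-row tibble.
#' @export
table1_fixture <- function() {
  rows <- table1_rows()
  terminal_names <- terminal_names_from_rows(rows)
  last_id <- vapply(rows$designed, function(s) {
    b <- suppressMessages(parse_barcode(s)); b$id[nrow(b)]
  }, character(1))
  dplyr::mutate(rows,
    truth = unname(terminal_names[last_id]),
    category_norm = dplyr::if_else(startsWith(.data$printed_category, "Positive"),
                                   "positive", "false_negative"),
    printed_complete_match = endsWith(.data$printed_category, "*"))
}

# terminal id -> order name, read off the positive rows
terminal_names_from_rows <- function(rows) {
  pos <- rows[startsWith(rows$printed_category, "Positive"), ]
  last_id <- vapply(pos$designed, function(s) {
    b <- suppressMessages(parse_barcode(s)); b$id[nrow(b)]
  }, character(1))
  nm <- pos$printed_result[!duplicated(last_id)]
  stats::setNames(nm, last_id[!duplicated(last_id)])
}

#' Code database of the embedded fixture
#'
#' Builds the designed-barcode trie of the fixture's 18 terminal
#' categories, with the study's published internal clade labels attached.
#'
#' @return a `code_db`.
#' @export
db_from_table1 <- function() {
  rows <- table1_fixture()
  dedup <- !duplicated(rows$truth)
  db_from_barcodes(rows$designed[dedup], rows$truth[dedup],
                   clade_labels = internal_clade_labels())
}

#' Evaluate the embedded fixture
#'
#' Runs every generated barcode of the fixture through the root-to-leaf
#' matcher against the designed-barcode database.
#'
#' @return an `apo_query_eval`.
#' @export
evaluate_table1 <- function() {
  rows <- table1_fixture()
  evaluate_queries(db_from_table1(),
                   tibble::tibble(species = rows$species,
                                  generated = rows$generated,
                                  truth = rows$truth))
}
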