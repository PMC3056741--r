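# Canonical reconstruction of chloroplast starch metabolism in
# Ostreococcus tauri: gluconeogenic entry from the Calvin-cycle GAP
# release point, ADP-glucose based glucan polymerization, granule
# assembly, GWD-primed degradation, and export of maltose and glucose.
#
# Glucan species are lumped chains with exact residue counts (20LG = a
# linear glucan of 20 glucose residues, 100BG = a branched glucan of 100
# residues, suffix "_g" = granule-incorporated, "_P" = GWD-phosphorylated),
# so every internal reaction balances carbon exactly.

# ---- constants ------------------------------------------------------------

#' Diel objective weights
#'
#' The weights of the linear diel objective
#' `Z = 1*CO2 + 10468.135*starch_ex + 963.325*maltose_out + 650*glucose_out`
#' (maximized). In the dark phase the CO2 weight is 0.
#' @keywords internal
.OBJ_W <- c(EX_CO2 = 1, EX_STARCH = 10468.135, EX_MAL = 963.325,
            EX_GLC = 650)

.MALTOSE_UB <- 166.5
.GLUCOSE_UB <- 122.45
# Carbon capacity of the light phase: chosen so that the shipped export
# bounds are exactly the optimum of the +/-1 diel step-function calibration
# (see calibrate_export_bounds and the methods vignette).
.CO2_UB <- 2 * (12 * .MALTOSE_UB + 6 * .GLUCOSE_UB)   # 5465.4 carbon/h
.CURRENCY_UB <- 1e5

# ---- metabolite inventory -------------------------------------------------

starch_metabolite_table <- function() {
  M <- function(id, name, carbons, currency = FALSE)
    data.frame(id = id, name = name, carbons = carbons,
               currency = currency, stringsAsFactors = FALSE)
  out <- rbind(
    M("CO2",     "carbon dioxide",                     1),
    M("GAP",     "glyceraldehyde 3-phosphate",         3),
    M("DHAP",    "dihydroxyacetone phosphate",         3),
    M("FBP",     "fructose 1,6-bisphosphate",          6),
    M("F6P",     "fructose 6-phosphate",               6),
    M("G6P",     "glucose 6-phosphate",                6),
    M("G1P",     "glucose 1-phosphate",                6),
    M("ADPG",    "ADP-glucose",                        6),
    M("GLC",     "glucose",                            6),
    M("MAL",     "maltose",                           12),
    M("MT3",     "maltotriose",                       18),
    M("MT4",     "maltotetraose",                     24),
    M("MT5",     "maltopentaose",                     30),
    M("MT7",     "maltoheptaose",                     42),
    M("10LG",    "linear glucan, 10 residues",        60),
    M("20LG",    "linear glucan, 20 residues",       120),
    M("30LG",    "linear glucan, 30 residues",       180),
    M("40LG",    "linear glucan, 40 residues",       240),
    M("50LG",    "linear glucan, 50 residues",       300),
    M("60LG",    "linear glucan, 60 residues",       360),
    M("80LG",    "linear glucan, 80 residues",       480),
    M("100LG",   "amylose-like linear glucan, 100 residues", 600),
    M("40BG",    "branched glucan, 40 residues",     240),
    M("60BG",    "branched glucan, 60 residues",     360),
    M("80BG",    "branched glucan, 80 residues",     480),
    M("100BG",   "branched glucan, 100 residues",    600),
    M("120BG",   "branched glucan, 120 residues",    720),
    M("100LG_g", "granule-bound 100LG",              600),
    M("100BG_g", "granule-bound 100BG",              600),
    M("120BG_g", "granule-bound 120BG",              720),
    M("100BG_P", "phosphorylated granule 100BG",     600),
    M("120BG_P", "phosphorylated granule 120BG",     720),
    M("ATP",     "ATP",    0, TRUE),
    M("ADP",     "ADP",    0, TRUE),
    M("AMP",     "AMP",    0, TRUE),
    M("Pi",      "orthophosphate",   0, TRUE),
    M("PPi",     "pyrophosphate",    0, TRUE)
  )
  out$compartment <- "chloroplast"
  out
}

# ---- gene table (starch pathway ORFs, with microarray availability) -------

#' The 43 starch-pathway genes of O. tauri
#'
#' Enzyme inventory of the reconstruction: EC number, enzyme, gene name,
#' ORF identifier and whether a diurnal expression profile is available
#' (29 of the 43 genes). Genes without profiles are imputed at the 0.01
#' expression floor throughout a simulation.
#'
#' @return A data frame with columns `ec`, `enzyme`, `gene_name`, `orf`,
#'   `expression_available`.
#' @export
starch_gene_table <- function() {
  G <- function(ec, enzyme, gene_name, orf, avail)
    data.frame(ec = ec, enzyme = enzyme, gene_name = gene_name, orf = orf,
               expression_available = avail, stringsAsFactors = FALSE)
  rbind(
    G("4.1.2.13", "Fructose-bisphosphate aldolase", "fbaI",  "Ot01g03020", TRUE),
    G("4.1.2.13", "Fructose-bisphosphate aldolase", "fbaI",  "Ot03g00610", TRUE),
    G("4.1.2.13", "Fructose-bisphosphate aldolase", "fbaII", "Ot10g01490", TRUE),
    G("3.1.3.11", "Fructose-1,6-bisphosphatase",    "",      "Ot03g00330", TRUE),
    G("3.1.3.11", "Fructose-1,6-bisphosphatase",    "",      "Ot14g01140", TRUE),
    G("5.3.1.1",  "Triosephosphate isomerase",      "",      "Ot09g00080", TRUE),
    G("5.3.1.9",  "Glucose-6-phosphate isomerase",  "",      "Ot11g02980", TRUE),
    G("5.4.2.2",  "Phosphoglucomutase",             "",      "Ot15g02630", TRUE),
    G("2.7.7.27", "ADP-glucose pyrophosphorylase",  "AGPLU1", "Ot07g03280", FALSE),
    G("2.7.7.27", "ADP-glucose pyrophosphorylase",  "agpsu1", "Ot07g02930", TRUE),
    G("2.7.7.27", "ADP-glucose pyrophosphorylase",  "agplu2", "Ot20g00490", FALSE),
    G("2.4.1.21", "Soluble starch synthase",        "SSIII-C", "Ot06g03410", FALSE),
    G("2.4.1.21", "Soluble starch synthase",        "SSIII-B", "Ot13g01250", TRUE),
    G("2.4.1.21", "Soluble starch synthase",        "SSII",    "Ot16g02790", TRUE),
    G("2.4.1.21", "Soluble starch synthase",        "SSI",     "Ot13g01230", TRUE),
    G("2.4.1.21", "Soluble starch synthase",        "SSIII-A", "Ot16g01560", TRUE),
    G("2.4.1.242", "Granule-bound starch synthase", "gbssI",   "Ot06g03200", TRUE),
    G("2.4.1.18", "Starch branching enzyme",        "SBEII",   "Ot03g00840", TRUE),
    G("2.4.1.18", "Starch branching enzyme",        "SBEI",    "Ot04g04110", TRUE),
    G("2.4.1.1",  "Starch phosphorylase",           "",        "Ot11g00280", FALSE),
    G("2.4.1.1",  "Starch phosphorylase",           "",        "Ot04g02110", TRUE),
    G("2.4.1.1",  "Starch phosphorylase",           "SPho1",   "Ot11g01020", FALSE),
    G("2.4.1.25", "Disproportionating enzyme",      "DPE1",    "Ot02g05750", TRUE),
    G("2.4.1.25", "Disproportionating enzyme",      "",        "Ot11g02290", FALSE),
    G("2.4.1.25", "Disproportionating enzyme",      "",        "Ot11g02300", FALSE),
    G("3.2.1.1",  "Alpha-amylase",                  "Aamy1",   "Ot16g00380", TRUE),
    G("3.2.1.1",  "Alpha-amylase",                  "",        "Ot02g05490", TRUE),
    G("3.2.1.1",  "Alpha-amylase",                  "Aamy2",   "Ot10g00260", TRUE),
    G("3.2.1.1",  "Alpha-amylase",                  "Aamy3",   "Ot07g02010", TRUE),
    G("3.2.1.2",  "Beta-amylase",                   "",        "Ot02g06980", TRUE),
    G("3.2.1.2",  "Beta-amylase",                   "Bamy2",   "Ot03g03190", TRUE),
    G("3.2.1.2",  "Beta-amylase",                   "bamy1",   "Ot03g03170", FALSE),
    G("3.2.1.68", "Isoamylase (debranching enzyme)", "dbe1 (Isa1)", "Ot14g02550", TRUE),
    G("3.2.1.68", "Isoamylase (debranching enzyme)", "Isa2",       "Ot02g07230", FALSE),
    G("3.2.1.68", "Isoamylase (debranching enzyme)", "dbeII (Isa3)", "Ot12g00310", TRUE),
    G("3.2.1.142", "Pullulanase",                   "spu",     "Ot01g03030", TRUE),
    G("2.7.9.4",  "Alpha-glucan, water dikinase (GWD)", "SR1-A", "Ot13g01510", TRUE),
    G("2.7.9.4",  "Alpha-glucan, water dikinase (GWD)", "R1 C",  "Ot16g02370", FALSE),
    G("2.7.9.4",  "Alpha-glucan, water dikinase (GWD)", "",      "Ot04g04170", FALSE),
    G("",         "Glucose transporter",            "",        "Ot03g05590", FALSE),
    G("",         "Glucose transporter",            "",        "Ot14g01870", FALSE),
    G("",         "Glucose transporter",            "",        "Ot08g01260", FALSE),
    G("",         "Maltose transporter",            "MEX1",    "Ot09g03160", TRUE)
  )
}

# ---- reaction inventory ---------------------------------------------------

# Equation DSL: "2 A + B -> C + 3 D"; "<->" marks reversible reactions.
.parse_equation <- function(eq) {
  rev <- grepl("<->", eq, fixed = TRUE)
  sides <- strsplit(eq, "<->|->")[[1]]
  if (length(sides) != 2L) stop("malformed equation: ", eq)
  term <- function(side, sign) {
    side <- trimws(side)
    if (side == "") return(numeric(0))
    parts <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (p in parts) {
      tk <- strsplit(p, "[ ]+")[[1]]
      if (length(tk) == 2L) { co <- as.numeric(tk[1]); id <- tk[2] }
      else { co <- 1; id <- tk[1] }
      out[id] <- sign * co
    }
    out
  }
  lhs <- term(sides[1], -1)
  rhs <- term(sides[2], +1)
  st <- lhs
  for (id in names(rhs)) st[id] <- (if (id %in% names(st)) st[id] else 0) + rhs[id]
  list(stoichiometry = st, reversible = rev)
}

starch_reaction_table <- function() {
  R <- function(id, name, eq, genes = "", ec = "", exchange = FALSE)
    data.frame(id = id, name = name, eq = eq, genes = genes, ec = ec,
               exchange = exchange, stringsAsFactors = FALSE)
  rbind(
    # -- gluconeogenic entry (from the Calvin-cycle GAP release point)
    R("CBC",      "CO2 fixation lump (Calvin cycle output)",
      "3 CO2 + 9 ATP -> GAP + 9 ADP + 8 Pi"),
    R("TPI",      "triosephosphate isomerase", "GAP <-> DHAP",
      "Ot09g00080", "5.3.1.1"),
    R("ALD",      "fructose-bisphosphate aldolase", "GAP + DHAP -> FBP",
      "Ot01g03020;Ot03g00610;Ot10g01490", "4.1.2.13"),
    R("FBPASE",   "fructose-1,6-bisphosphatase", "FBP -> F6P + Pi",
      "Ot03g00330;Ot14g01140", "3.1.3.11"),
    R("GPI",      "glucose-6-phosphate isomerase", "F6P <-> G6P",
      "Ot11g02980", "5.3.1.9"),
    R("PGM",      "phosphoglucomutase", "G6P <-> G1P",
      "Ot15g02630", "5.4.2.2"),
    R("AGP",      "ADP-glucose pyrophosphorylase",
      "G1P + ATP -> ADPG + PPi",
      "Ot07g03280;Ot07g02930;Ot20g00490", "2.7.7.27"),
    R("PPA",      "inorganic pyrophosphatase lump", "PPi -> 2 Pi"),
    R("ADK",      "adenylate kinase lump", "ATP + AMP -> 2 ADP"),
    # -- soluble starch synthase: malto-oligosaccharide priming (SSI)
    R("SS_DENOVO", "SS de novo maltopentaose priming",
      "5 ADPG -> MT5 + 5 ADP", "Ot13g01230;Ot16g02790", "2.4.1.21"),
    R("SS_MT3",   "SS elongation MT3 to MT5",
      "MT3 + 2 ADPG -> MT5 + 2 ADP", "Ot13g01230;Ot16g02790", "2.4.1.21"),
    R("SS_MT5",   "SS elongation MT5 to MT7",
      "MT5 + 2 ADPG -> MT7 + 2 ADP", "Ot13g01230;Ot16g02790", "2.4.1.21"),
    R("SS_MT7",   "SS elongation MT7 to 10LG",
      "MT7 + 3 ADPG -> 10LG + 3 ADP", "Ot13g01230;Ot16g02790", "2.4.1.21"),
    R("SS_MT4",   "SS elongation MT4 to MT5",
      "MT4 + ADPG -> MT5 + ADP", "Ot13g01230;Ot16g02790", "2.4.1.21"),
    # -- soluble chain extension (SSII)
    R("SS_10_20", "SS elongation 10LG to 20LG",
      "10LG + 10 ADPG -> 20LG + 10 ADP", "Ot16g02790;Ot16g01560", "2.4.1.21"),
    R("SS_20_30", "SS elongation 20LG to 30LG",
      "20LG + 10 ADPG -> 30LG + 10 ADP", "Ot16g02790;Ot16g01560", "2.4.1.21"),
    R("SS_30_40", "SS elongation 30LG to 40LG",
      "30LG + 10 ADPG -> 40LG + 10 ADP", "Ot16g02790;Ot16g01560", "2.4.1.21"),
    # -- long-chain extension (SSIII-A)
    R("SS_40_50", "SS elongation 40LG to 50LG",
      "40LG + 10 ADPG -> 50LG + 10 ADP", "Ot16g01560", "2.4.1.21"),
    R("SS_50_60", "SS elongation 50LG to 60LG",
      "50LG + 10 ADPG -> 60LG + 10 ADP", "Ot16g01560", "2.4.1.21"),
    R("SS_60_80", "SS elongation 60LG to 80LG",
      "60LG + 20 ADPG -> 80LG + 20 ADP", "Ot16g01560", "2.4.1.21"),
    # -- branched-glucan extension (SSIII-B / SSIII-C)
    R("SSB_40_60", "SS elongation 40BG to 60BG",
      "40BG + 20 ADPG -> 60BG + 20 ADP", "Ot13g01250", "2.4.1.21"),
    R("SSB_60_80", "SS elongation 60BG to 80BG",
      "60BG + 20 ADPG -> 80BG + 20 ADP", "Ot13g01250", "2.4.1.21"),
    R("SSB_80_100", "SS elongation 80BG to 100BG",
      "80BG + 20 ADPG -> 100BG + 20 ADP", "Ot13g01250;Ot06g03410", "2.4.1.21"),
    R("SSB_100_120", "SS elongation 100BG to 120BG",
      "100BG + 20 ADPG -> 120BG + 20 ADP", "Ot13g01250;Ot06g03410", "2.4.1.21"),
    # -- granule-bound starch synthase: amylose
    R("GBSS_100LG", "GBSSI amylose elongation 80LG to 100LG",
      "80LG + 20 ADPG -> 100LG + 20 ADP", "Ot06g03200", "2.4.1.242"),
    R("GBSS_GRAN", "100LG_g: amylose granule incorporation",
      "100LG -> 100LG_g", "Ot06g03200", "2.4.1.242"),
    # -- starch branching enzyme
    R("SBE_40",   "SBE branching of 40LG", "40LG -> 40BG",
      "Ot03g00840", "2.4.1.18"),
    R("SBE_60",   "SBE branching of 60LG", "60LG -> 60BG",
      "Ot03g00840;Ot04g04110", "2.4.1.18"),
    R("SBE_80",   "SBE branching of 80LG", "80LG -> 80BG",
      "Ot04g04110", "2.4.1.18"),
    # -- amylopectin granule incorporation (crystallization at the surface)
    R("GRAN_100BG", "100BG_g: amylopectin granule incorporation",
      "100BG -> 100BG_g", "Ot03g00840;Ot06g03410", "2.4.1.18"),
    R("GRAN_120BG", "120BG_g: amylopectin granule incorporation",
      "120BG -> 120BG_g", "Ot04g04110;Ot06g03410", "2.4.1.18"),
    # -- degradation initiation: granule phosphorylation by GWD
    R("GWD_100BG", "GWD phosphorylation of granule 100BG",
      "100BG_g + ATP -> 100BG_P + AMP + Pi",
      "Ot13g01510;Ot16g02370", "2.7.9.4"),
    R("GWD_120BG", "GWD phosphorylation of granule 120BG",
      "120BG_g + ATP -> 120BG_P + AMP + Pi",
      "Ot13g01510;Ot04g04170", "2.7.9.4"),
    # -- debranching: chains plus short A-chain stubs (MOS)
    R("ISA_100BG_P", "100BGs_Pto20LG: debranching of phospho-100BG",
      "100BG_P -> 20LG + 16 MT5 + Pi", "Ot12g00310", "3.2.1.68"),
    R("ISA_120BG_P", "debranching of phospho-120BG",
      "120BG_P -> 2 30LG + 12 MT5 + Pi", "Ot12g00310", "3.2.1.68"),
    R("PUL_120BG_P", "pullulanase debranching of phospho-120BG",
      "120BG_P -> 2 20LG + 16 MT5 + Pi", "Ot01g03030", "3.2.1.142"),
    R("ISA_60BG", "60BGto20LG: debranching of soluble 60BG",
      "60BG -> 20LG + 8 MT5", "Ot14g02550", "3.2.1.68"),
    R("ISA_40BG", "debranching of soluble 40BG",
      "40BG -> 20LG + 4 MT5", "Ot14g02550", "3.2.1.68"),
    R("ISA_80BG", "debranching of soluble 80BG",
      "80BG -> 20LG + 12 MT5", "Ot02g07230", "3.2.1.68"),
    R("ISA_80BG_40", "partial debranching of soluble 80BG",
      "80BG -> 40LG + 8 MT5", "Ot02g07230", "3.2.1.68"),
    # -- alpha-amylase hydrolysis
    R("AMY_100LG_G", "alpha-amylolysis of granule amylose",
      "100LG_g -> 4 20LG + 4 MT5", "Ot07g02010", "3.2.1.1"),
    R("AMY_100LG", "alpha-amylolysis of 100LG",
      "100LG -> 5 20LG", "Ot16g00380", "3.2.1.1"),
    R("AMY_80LG", "alpha-amylolysis of 80LG",
      "80LG -> 4 20LG", "Ot16g00380", "3.2.1.1"),
    R("AMY_60LG", "alpha-amylolysis of 60LG",
      "60LG -> 3 20LG", "Ot02g05490", "3.2.1.1"),
    R("AMY_40LG", "alpha-amylolysis of 40LG",
      "40LG -> 2 20LG", "Ot02g05490", "3.2.1.1"),
    R("AMY_30LG", "alpha-amylolysis of 30LG",
      "30LG -> 10LG + 20LG", "Ot10g00260", "3.2.1.1"),
    R("AMY_20LG", "alpha-amylolysis of 20LG",
      "20LG -> 2 10LG", "Ot10g00260", "3.2.1.1"),
    R("AMY_10LG", "alpha-amylolysis of 10LG",
      "10LG -> 2 MT5", "Ot07g02010", "3.2.1.1"),
    R("AMY_20LG_MT4", "alpha-amylolysis of 20LG to maltotetraose",
      "20LG -> 5 MT4", "Ot07g02010", "3.2.1.1"),
    # -- beta-amylase: maltose release (stops near branch stubs: MT3 left)
    R("BAMY_20LG", "beta-amylolysis of 20LG",
      "20LG -> 10 MAL", "Ot03g03190", "3.2.1.2"),
    R("BAMY_30LG", "beta-amylolysis of 30LG",
      "30LG -> 12 MAL + 2 MT3", "Ot02g06980;Ot03g03190", "3.2.1.2"),
    R("BAMY_MT5", "beta-amylolysis of maltopentaose",
      "MT5 -> MAL + MT3", "Ot02g06980;Ot03g03170", "3.2.1.2"),
    R("BAMY_MT7", "beta-amylolysis of maltoheptaose",
      "MT7 -> 2 MAL + MT3", "Ot03g03170", "3.2.1.2"),
    # -- disproportionating enzyme (DPE1): the only glucose source
    R("DPE_MT3", "DPE1 disproportionation of maltotriose",
      "2 MT3 -> GLC + MT5", "Ot02g05750;Ot11g02290", "2.4.1.25"),
    R("DPE_MT3_MT5", "DPE1 maltosyl transfer MT3 to MT5",
      "MT3 + MT5 -> GLC + MT7", "Ot02g05750;Ot11g02300", "2.4.1.25"),
    # -- starch phosphorylase: phosphorolysis to G1P
    R("SPHO_20LG", "phosphorolysis of 20LG",
      "20LG + 10 Pi -> 10 G1P + 10LG", "Ot11g00280", "2.4.1.1"),
    R("SPHO_10LG", "phosphorolysis of 10LG",
      "10LG + 5 Pi -> 5 G1P + MT5", "Ot11g00280", "2.4.1.1"),
    R("SPHO_30LG", "phosphorolysis of 30LG",
      "30LG + 10 Pi -> 10 G1P + 20LG", "Ot04g02110", "2.4.1.1"),
    R("SPHO_40LG", "phosphorolysis of 40LG",
      "40LG + 10 Pi -> 10 G1P + 30LG", "Ot04g02110", "2.4.1.1"),
    R("SPHO_50LG", "phosphorolysis of 50LG",
      "50LG + 10 Pi -> 10 G1P + 40LG", "Ot04g02110", "2.4.1.1"),
    R("SPHO_60LG", "phosphorolysis of 60LG",
      "60LG + 20 Pi -> 20 G1P + 40LG", "Ot11g01020", "2.4.1.1"),
    R("SPHO_100BG_P", "granule-surface phosphorolysis of phospho-100BG",
      "100BG_P + 80 Pi -> 80 G1P + 4 MT5", "Ot04g02110;Ot11g00280", "2.4.1.1"),
    R("SPHO_120BG_P", "granule-surface phosphorolysis of phospho-120BG",
      "120BG_P + 90 Pi -> 90 G1P + 6 MT5", "Ot04g02110;Ot11g01020", "2.4.1.1"),
    # -- exchange fluxes b1..b6
    R("EX_CO2", "b1: CO2 uptake", " -> CO2", exchange = TRUE),
    R("EX_STARCH", "b2: starch granule exchange",
      "100LG_g + 4 100BG_g + 2 120BG_g <-> ", exchange = TRUE),
    R("EX_MAL", "b3: maltose export (MEX1)", "MAL -> ",
      "Ot09g03160", exchange = TRUE),
    R("EX_GLC", "b4: glucose export", "GLC -> ",
      "Ot03g05590;Ot14g01870;Ot08g01260", exchange = TRUE),
    R("EX_PI", "b5: phosphate exchange", "Pi <-> ", exchange = TRUE),
    R("EX_ATP", "b6: photophosphorylation ATP regeneration",
      "ADP + Pi -> ATP", exchange = TRUE)
  )
}

# ---- model constructor ----------------------------------------------------

#' Build the canonical O. tauri starch metabolism model
#'
#' Constructs the mass-balanced reconstruction of chloroplast starch
#' metabolism: 37 metabolites, 69 reactions (63 internal + 6 exchange
#' fluxes b1-b6) and 43 gene associations. Starch leaves the system as a
#' fixed granule bundle `100LG_g + 4 100BG_g + 2 120BG_g`, i.e. one unit
#' of starch-exchange flux carries 740 glucosyl residues (4440 carbons).
#'
#' Default internal upper bounds follow a single capacity rule: with `Q =
#' co2_upper/6` the light-phase glucosyl capacity, every internal reaction
#' gets `ub = Q / g` where `g` is the glucosyl consumed per unit flux, so
#' each step can individually carry the model's full carbon throughput
#' ("bounds as a proportion of the maximum starch production rate").
#' Currency-only reactions are effectively unbounded.
#'
#' @param co2_upper upper bound of the CO2 uptake flux b1 (carbon/h in
#'   normalized units).
#' @param maltose_upper,glucose_upper export bounds of b3/b4 (the
#'   step-function-calibrated defaults are 166.5 and 122.45).
#' @param currency_upper bound used for currency-only fluxes.
#'
#' @return An object of class `starch_model`: a list with `metabolites`,
#'   `reactions` (including list-columns `stoichiometry` and `gene_ids`
#'   and the default bounds), `gene_table` and the light-phase `objective`.
#' @examples
#' mod <- build_starch_model()
#' nrow(mod$reactions)          # 69
#' nrow(mod$metabolites)        # 37
#' @export
build_starch_model <- function(co2_upper = .CO2_UB,
                               maltose_upper = .MALTOSE_UB,
                               glucose_upper = .GLUCOSE_UB,
                               currency_upper = .CURRENCY_UB) {
  mets <- starch_metabolite_table()
  rtab <- starch_reaction_table()
  genes <- starch_gene_table()

  parsed <- lapply(rtab$eq, .parse_equation)
  stoich <- lapply(parsed, `[[`, "stoichiometry")
  revs <- vapply(parsed, `[[`, logical(1), "reversible")
  gene_ids <- lapply(strsplit(rtab$genes, ";", fixed = TRUE),
                     function(g) g[nzchar(g)])

  carbons <- stats::setNames(mets$carbons, mets$id)
  currency <- stats::setNames(mets$currency, mets$id)

  Qg <- co2_upper / 6   # glucosyl capacity per hour
  n <- nrow(rtab)
  lower <- numeric(n); upper <- numeric(n)
  for (i in seq_len(n)) {
    st <- stoich[[i]]
    unknown <- setdiff(names(st), mets$id)
    if (length(unknown))
      stop("reaction ", rtab$id[i], " uses unknown metabolites: ",
           paste(unknown, collapse = ", "))
    id <- rtab$id[i]
    if (id == "EX_CO2") { lower[i] <- 0; upper[i] <- co2_upper; next }
    if (id == "EX_MAL") { lower[i] <- 0; upper[i] <- maltose_upper; next }
    if (id == "EX_GLC") { lower[i] <- 0; upper[i] <- glucose_upper; next }
    if (id == "EX_PI")  { lower[i] <- -currency_upper; upper[i] <- currency_upper; next }
    if (id == "EX_ATP") { lower[i] <- 0; upper[i] <- currency_upper; next }
    # glucosyl consumed per unit flux (non-currency substrates)
    sub <- st[st < 0]
    sub <- sub[!currency[names(sub)]]
    g <- if (length(sub)) sum(-sub * carbons[names(sub)]) / 6 else 0
    if (id == "EX_STARCH") {
      upper[i] <- Qg / g
      lower[i] <- -upper[i]
      next
    }
    if (g == 0) {       # currency-only internal lump
      upper[i] <- currency_upper
    } else {
      upper[i] <- Qg / g
    }
    lower[i] <- if (revs[i]) -upper[i] else 0
  }

  reactions <- data.frame(
    id = rtab$id, name = rtab$name, ec = rtab$ec,
    lower_bound = lower, upper_bound = upper,
    default_lower = lower, default_upper = upper,
    reversible = revs, is_exchange = rtab$exchange,
    stringsAsFactors = FALSE
  )
  reactions$stoichiometry <- stoich
  reactions$gene_ids <- gene_ids

  model <- structure(
    list(metabolites = mets, reactions = reactions, gene_table = genes,
         objective = .OBJ_W, co2_upper = co2_upper),
    class = "starch_model"
  )
  validate_starch_model(model)
  model
}

#' Validate the structural invariants of a starch model
#'
#' Checks id uniqueness, bound sanity, dimension agreement of the
#' stoichiometric matrix, gene-table closure (every reaction gene appears
#' in the gene table and vice versa) and internal carbon conservation.
#'
#' @param model a `starch_model`.
#' @return `model`, invisibly; errors on violation.
#' @export
validate_starch_model <- function(model) {
  mets <- model$metabolites; rx <- model$reactions
  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(rx$id)) stop("duplicate reaction ids")
  if (any(rx$lower_bound > rx$upper_bound))
    stop("lower bound exceeds upper bound for: ",
         paste(rx$id[rx$lower_bound > rx$upper_bound], collapse = ", "))
  S <- stoichiometric_matrix(model)
  if (!identical(dim(S), c(nrow(mets), nrow(rx))))
    stop("stoichiometric matrix dimensions disagree with the inventory")
  rx_genes <- unique(unlist(rx$gene_ids))
  missing <- setdiff(rx_genes, model$gene_table$orf)
  if (length(missing))
    stop("reaction genes missing from gene table: ",
         paste(missing, collapse = ", "))
  orphan <- setdiff(model$gene_table$orf, rx_genes)
  if (length(orphan))
    stop("gene table ORFs mapped to no reaction: ",
         paste(orphan, collapse = ", "))
  bad <- validate_carbon_balance(model)
  if (length(bad))
    stop("carbon not conserved in: ", paste(bad, collapse = ", "))
  invisible(model)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `starch_model`.
#' @return A dense numeric matrix, metabolites in rows, reactions in
#'   columns, entry (i, j) the signed coefficient of metabolite i in
#'   reaction j (negative = consumed).
#' @export
stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id
  rx <- model$reactions
  S <- matrix(0, nrow = length(mets), ncol = nrow(rx),
              dimnames = list(mets, rx$id))
  for (j in seq_len(nrow(rx))) {
    st <- rx$stoichiometry[[j]]
    if (length(st)) S[names(st), j] <- st
  }
  S
}

#' Check carbon conservation of all internal reactions
#'
#' Sums coefficient x carbon-count over the non-currency metabolites of
#' every internal (non-exchange) reaction. Exchange reactions move mass
#' across the boundary and are skipped.
#'
#' @param model a `starch_model`.
#' @return Character vector of reaction ids violating carbon balance
#'   (empty if the model is mass-consistent).
#' @export
validate_carbon_balance <- function(model) {
  carbons <- stats::setNames(model$metabolites$carbons, model$metabolites$id)
  currency <- stats::setNames(model$metabolites$currency, model$metabolites$id)
  bad <- character(0)
  for (j in seq_len(nrow(model$reactions))) {
    if (model$reactions$is_exchange[j]) next
    st <- model$reactions$stoichiometry[[j]]
    unknown <- setdiff(names(st), names(carbons))
    if (length(unknown))
      stop("reaction ", model$reactions$id[j],
           " references unknown metabolite: ",
           paste(unknown, collapse = ", "))
    keep <- !currency[names(st)]
    if (abs(sum(st[keep] * carbons[names(st)[keep]])) > 1e-9)
      bad <- c(bad, model$reactions$id[j])
  }
  bad
}

#' Glucosyl residues carried by one unit of starch-exchange flux
#'
#' Derived from the granule bundle stoichiometry of `EX_STARCH`
#' (canonically 100 + 4 x 100 + 2 x 120 = 740 residues, 4440 carbons).
#'
#' @param model a `starch_model`.
#' @return Number of glucosyl residues per unit flux.
#' @export
starch_unit_residues <- function(model) {
  st <- model$reactions$stoichiometry[[match("EX_STARCH", model$reactions$id)]]
  carbons <- stats::setNames(model$metabolites$carbons, model$metabolites$id)
  sum(-st * carbons[names(st)]) / 6
}

# ---- small accessors ------------------------------------------------------

#' @export
print.starch_model <- function(x, ...) {
  nex <- sum(x$reactions$is_exchange)
  cat("Starch metabolism model (O. tauri chloroplast)\n")
  cat("  metabolites:", nrow(x$metabolites),
      " reactions:", nrow(x$reactions),
      " (", nex, "exchange )\n")
  cat("  genes:", length(unique(unlist(x$reactions$gene_ids))),
      " ( expression available:",
      sum(x$gene_table$expression_available), ")\n")
  cat("  starch unit:", starch_unit_residues(x), "glucosyl residues\n")
  invisible(x)
}

#' @export
summary.starch_model <- function(object, ...) {
  rx <- object$reactions
  data.frame(
    reaction = rx$id, name = rx$name, ec = rx$ec,
    lower = rx$lower_bound, upper = rx$upper_bound,
    exchange = rx$is_exchange,
    genes = vapply(rx$gene_ids, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
}

.rx_index <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", id)
  i
}
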