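# Combinatorial library design: triazole ligand enumeration from building
# blocks, metal-complex assembly against scaffold compatibility, and 96-well
# plate mapping.

AMINE_ROLES <- c("primary-amine", "2-picolylamine")
ALKYNE_ROLES <- c("2-alkynylpyridine", "aryl-alkyne")
BB_ROLES <- c(AMINE_ROLES, ALKYNE_ROLES)

#' Read a building-block registry
#'
#' A registry is tabular with columns `id`, `role`, `formula` (Hill notation),
#' and optionally `smiles`, `name`, `placeholder`. Roles come from the closed
#' set primary-amine / 2-alkynylpyridine / 2-picolylamine / aryl-alkyne.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_registry <- function(path) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_registry(reg)
}

validate_registry <- function(reg) {
  stopifnot(all(c("id", "role", "formula") %in% names(reg)))
  if (anyDuplicated(reg$id)) {
    stop("duplicate building-block id(s): ",
         paste0(unique(reg$id[duplicated(reg$id)]), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(reg$role), BB_ROLES)
  if (length(bad)) stop("unknown role(s): ", paste0(bad, collapse = ", "), call. = FALSE)
  for (f in reg$formula) parse_formula(f) # validates counts >= 0
  if (is.null(reg$name)) reg$name <- reg$id
  if (is.null(reg$smiles)) reg$smiles <- NA_character_
  reg
}

#' Default building-block registries
#'
#' The registries shipped with the package: 24 primary amines and four
#' 2-alkynylpyridines for the triazole-4-pyridine (Tz-4-P) class, and eight
#' 2-picolylamines and twelve aryl alkynes for the
#' triazole-1-methylpyridine (Tz-1-MP) class. Blocks not identifiable from the
#' campaign description carry `placeholder = TRUE`: their formulas are
#' documented synthetic stand-ins and freely user-editable; every count and
#' pipeline behaviour is registry-independent.
#'
#' @param class `"Tz-4-P"` or `"Tz-1-MP"`.
#' @return A list with elements `amines` and `alkynes` (data frames).
#' @export
default_building_blocks <- function(class = c("Tz-4-P", "Tz-1-MP")) {
  class <- match.arg(class)
  stub <- if (class == "Tz-4-P") c("amines_tz4p", "alkynes_tz4p") else c("amines_tz1mp", "alkynes_tz1mp")
  paths <- vapply(stub, function(s) {
    system.file("extdata", paste0(s, ".csv"), package = "metalloscreen", mustWork = TRUE)
  }, character(1))
  list(amines = read_registry(paths[[1]]), alkynes = read_registry(paths[[2]]))
}

#' Couple an amine and an alkyne into a triazole ligand
#'
#' In-situ azide formation from the primary amine followed by CuAAC
#' cycloaddition conserves all parent atoms except that two hydrogens leave
#' with the diazo transfer and two nitrogens stay in the triazole ring:
#' product formula = amine + alkyne + 2 N - 2 H, exactly.
#'
#' @param amine,alkyne One-row data frames or lists with `id`, `role`,
#'   `formula`.
#' @return A list of class `ligand_spec` with `id` (amine id then alkyne id),
#'   `ligand_class`, `formula` (`chem_formula`) and `parent_ids`.
#' @examples
#' couple_triazole(list(id = "M4", role = "primary-amine", formula = "C7H9N"),
#'                 list(id = "Y1", role = "2-alkynylpyridine", formula = "C7H5N"))
#' @export
couple_triazole <- function(amine, alkyne) {
  amine <- as.list(amine)
  alkyne <- as.list(alkyne)
  pairing <- paste(amine$role[[1]], alkyne$role[[1]], sep = " + ")
  ligand_class <- switch(
    pairing,
    "primary-amine + 2-alkynylpyridine" = "Tz-4-P",
    "2-picolylamine + aryl-alkyne" = "Tz-1-MP",
    stop("invalid pairing: ", pairing, call. = FALSE)
  )
  total <- combine_formula(amine$formula[[1]], parse_formula(alkyne$formula[[1]]))
  product <- combine_formula(total, c(N = 2, H = -2)) # underflow caught here
  structure(list(id = paste0(amine$id[[1]], alkyne$id[[1]]),
                 ligand_class = ligand_class,
                 formula = product,
                 parent_ids = c(amine$id[[1]], alkyne$id[[1]])),
            class = "ligand_spec")
}

#' Enumerate the full amine x alkyne ligand cross
#'
#' Deterministic amine-major ordering: all alkynes for the first amine, then
#' the second, and so on. Empty inputs give an empty result.
#'
#' @param amines,alkynes Registry data frames (see [read_registry()]).
#' @return A data frame with one row per ligand: `id`, `ligand_class`,
#'   `formula`, `amine_id`, `alkyne_id`.
#' @export
enumerate_ligands <- function(amines, alkynes) {
  empty <- data.frame(id = character(0), ligand_class = character(0),
                      formula = character(0), amine_id = character(0),
                      alkyne_id = character(0), stringsAsFactors = FALSE)
  if (!nrow(amines) || !nrow(alkynes)) return(empty)
  amines <- validate_registry(amines)
  alkynes <- validate_registry(alkynes)
  if (length(unique(amines$role)) != 1L || length(unique(alkynes$role)) != 1L) {
    stop("registry roles must be homogeneous per list", call. = FALSE)
  }
  rows <- vector("list", nrow(amines) * nrow(alkynes))
  k <- 0L
  for (i in seq_len(nrow(amines))) {
    for (j in seq_len(nrow(alkynes))) {
      lig <- couple_triazole(amines[i, ], alkynes[j, ])
      k <- k + 1L
      rows[[k]] <- data.frame(id = lig$id, ligand_class = lig$ligand_class,
                              formula = format_formula(lig$formula),
                              amine_id = amines$id[i], alkyne_id = alkynes$id[j],
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' The five metal scaffolds
#'
#' Cation compositions of the metal fragment retained on complexation, the
#' axial ligand where one is installed (1-methylbenzimidazole, BeMeIm =
#' C8H8N2, for the fac-tricarbonyl Re and Mn scaffolds), and the ligand-class
#' compatibility matrix: Tz-4-P coordinates to all five scaffolds, Tz-1-MP
#' only to IrCp* and RuCy.
#'
#' @return A data frame with columns `id`, `fragment_formula`,
#'   `fragment_charge`, `axial_formula`, `compatible_classes`
#'   (comma-separated).
#' @export
default_scaffolds <- function() {
  data.frame(
    id = c("IrCN", "IrCp*", "RuCy", "Re(CO)3", "Mn(CO)3"),
    fragment_formula = c("IrC22H16N2", "IrC10H15Cl", "RuC10H14Cl", "ReC3O3", "MnC3O3"),
    fragment_charge = c(1L, 1L, 1L, 1L, 1L),
    axial_formula = c("", "", "", "C8H8N2", "C8H8N2"),
    compatible_classes = c("Tz-4-P", "Tz-4-P,Tz-1-MP", "Tz-4-P,Tz-1-MP",
                           "Tz-4-P", "Tz-4-P"),
    stringsAsFactors = FALSE
  )
}

#' Assemble metal complexes from ligands and scaffolds
#'
#' One complex per (ligand, scaffold) pair whose ligand class is in the
#' scaffold's compatibility set; incompatible pairs are skipped silently.
#' Complex composition is exact integer bookkeeping:
#' fragment + ligand + axial; the charge is the fragment charge.
#'
#' @param ligands Ligand data frame from [enumerate_ligands()].
#' @param scaffolds Scaffold data frame (default [default_scaffolds()]).
#' @return A data frame: `id` (e.g. `"Re(CO)3(M1Y1)"`), `scaffold_id`,
#'   `ligand_id`, `ligand_class`, `formula`, `charge`.
#' @export
assemble_complexes <- function(ligands, scaffolds = default_scaffolds()) {
  out <- vector("list", nrow(scaffolds))
  for (s in seq_len(nrow(scaffolds))) {
    compat <- strsplit(scaffolds$compatible_classes[s], ",", fixed = TRUE)[[1]]
    sel <- ligands[ligands$ligand_class %in% trimws(compat), , drop = FALSE]
    if (!nrow(sel)) next
    frag <- parse_formula(scaffolds$fragment_formula[s])
    axial <- parse_formula(scaffolds$axial_formula[s])
    formula <- vapply(sel$formula, function(lf) {
      format_formula(combine_formula(combine_formula(frag, parse_formula(lf)), axial))
    }, character(1), USE.NAMES = FALSE)
    out[[s]] <- data.frame(
      id = sprintf("%s(%s)", scaffolds$id[s], sel$id),
      scaffold_id = scaffolds$id[s], ligand_id = sel$id,
      ligand_class = sel$ligand_class, formula = formula,
      charge = scaffolds$fragment_charge[s], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(id = character(0), scaffold_id = character(0),
                      ligand_id = character(0), ligand_class = character(0),
                      formula = character(0), charge = integer(0),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Assign compounds to a 96-well plate
#'
#' Row-major fill: A1..A12, then B1..B12, down to H12.
#'
#' @param compounds Character vector of at most 96 compound ids.
#' @param plate_id Plate label.
#' @return A data frame `well`, `compound_id` with attribute `plate_id`.
#' @export
assign_plate <- function(compounds, plate_id = "plate1") {
  n <- length(compounds)
  if (n > 96L) stop("plate overflow: ", n, " compounds for 96 wells", call. = FALSE)
  wells <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  structure(data.frame(well = wells[seq_len(n)], compound_id = compounds,
                       stringsAsFactors = FALSE),
            plate_id = plate_id)
}

#' Reconstruct the full campaign
#'
#' Enumerates both ligand libraries from the shipped registries, assembles the
#' antibacterial-screen complexes (Tz-4-P against all five scaffolds, Tz-1-MP
#' against IrCp* and RuCy) and the transfer-hydrogenation subset (both ligand
#' classes against RuCy and IrCp*).
#'
#' @return A list with `ligands_tz4p`, `ligands_tz1mp`, `ligands`,
#'   `complexes`, `th_screen` and a named integer vector `counts`.
#' @export
enumerate_campaign <- function() {
  bb4 <- default_building_blocks("Tz-4-P")
  bb1 <- default_building_blocks("Tz-1-MP")
  lig4 <- enumerate_ligands(bb4$amines, bb4$alkynes)
  lig1 <- enumerate_ligands(bb1$amines, bb1$alkynes)
  ligands <- rbind(lig4, lig1)
  scaffolds <- default_scaffolds()
  complexes <- assemble_complexes(ligands, scaffolds)
  th <- assemble_complexes(ligands, scaffolds[scaffolds$id %in% c("RuCy", "IrCp*"), ])
  list(
    ligands_tz4p = lig4, ligands_tz1mp = lig1, ligands = ligands,
    complexes = complexes, th_screen = th,
    counts = c(tz4p_ligands = nrow(lig4), tz1mp_ligands = nrow(lig1),
               ligands = nrow(ligands),
               tz4p_complexes = sum(complexes$ligand_class == "Tz-4-P"),
               complexes = nrow(complexes), th_screen = nrow(th))
  )
}
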