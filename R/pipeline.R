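#' Analysis configuration
#'
#' Bundles every tunable parameter of the pipeline with its default:
#' cluster half-width `window` (2 alignment columns), interface distance
#' `interface_cutoff` (4 angstroms, inclusive), phospho-ubiquitin
#' `crosstalk_window` (5 residues, inclusive), conditional score weights
#' `w1`/`w2` (2 each) and `nkc_mode`, projection `n_bins` (5),
#' `conservation_scope` for feature conservation, candidate
#' `acceptor_residues` for enrichment (S/T; add Y for generality), and the
#' random `seed`.
#'
#' @param window integer >= 0.
#' @param interface_cutoff positive distance in angstroms.
#' @param crosstalk_window integer residues.
#' @param w1,w2 conditional weights >= 1.
#' @param nkc_mode `"count"` or `"binary"` (see [integrative_score()]).
#' @param n_bins integer >= 1.
#' @param conservation_scope `"all"` or `"query"`.
#' @param acceptor_residues candidate letters for enrichment.
#' @param seed integer.
#' @return A validated `analysis_config` list.
#' @export
analysis_config <- function(window = 2L, interface_cutoff = 4.0,
                            crosstalk_window = 5L, w1 = 2, w2 = 2,
                            nkc_mode = c("count", "binary"), n_bins = 5L,
                            conservation_scope = c("all", "query"),
                            acceptor_residues = c("S", "T"), seed = 1L) {
  nkc_mode <- match.arg(nkc_mode)
  conservation_scope <- match.arg(conservation_scope)
  if (window < 0L) abort("window must be >= 0")
  if (interface_cutoff <= 0) abort("interface_cutoff must be positive")
  if (n_bins < 1L) abort("n_bins must be >= 1")
  if (w1 < 1 || w2 < 1) abort("weights must be >= 1")
  structure(list(
    window = as.integer(window), interface_cutoff = interface_cutoff,
    crosstalk_window = as.integer(crosstalk_window), w1 = w1, w2 = w2,
    nkc_mode = nkc_mode, n_bins = as.integer(n_bins),
    conservation_scope = conservation_scope,
    acceptor_residues = acceptor_residues, seed = as.integer(seed)
  ), class = "analysis_config")
}

#' Run the hotspot-prioritization pipeline end-to-end
#'
#' Stages: (optional) profile-to-profile merge of a second sub-alignment;
#' PTM validation and MAP construction; (optional) interface detection from
#' a two-chain structure; feature computation; Integrative Score, ranking
#' and binning; (optional) region enrichment; crosstalk pairs; (optional)
#' structural projection. Stages whose inputs are missing are skipped with
#' a warning, never an error. All outputs are deterministic given
#' identical inputs and configuration.
#'
#' @param alignment a `ptm_alignment` or path to an aligned FASTA file.
#' @param ptms a validated PTM tibble or path to a PTM TSV.
#' @param profile optional second `ptm_alignment` (or path) merged into
#'   `alignment` via [profile_align()] before mapping.
#' @param regions optional region tibble or TSV path.
#' @param structure_path optional PDB file with the two chains.
#' @param chain_a,chain_b chain identifiers in `structure_path`.
#' @param structure_protein the family member `chain_a` represents.
#' @param config an [analysis_config()].
#' @param out_dir optional output directory; when given, writes
#'   `features.tsv`, `ranks.tsv`, `enrichment.tsv`, `crosstalk.tsv`,
#'   `projected.pdb` (if structure given) and `manifest.json`.
#' @return A list: `alignment` (merged), `maps`, `features`, `scores`,
#'   `enrichment`, `crosstalk`, `interfaces`, `manifest`.
#' @export
run_pipeline <- function(alignment, ptms, profile = NULL, regions = NULL,
                         structure_path = NULL, chain_a = "A", chain_b = "B",
                         structure_protein = NULL,
                         config = analysis_config(), out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  input_paths <- character(0L)
  if (is.character(alignment)) {
    input_paths <- c(input_paths, alignment)
    alignment <- read_alignment(alignment)
  }
  if (!is.null(profile)) {
    if (is.character(profile)) {
      input_paths <- c(input_paths, profile)
      profile <- read_alignment(profile)
    }
    alignment <- profile_align(alignment, profile)
  }
  if (is.character(ptms)) {
    input_paths <- c(input_paths, ptms)
    ptms <- read_ptm_table(ptms, alignment)
  } else {
    ptms <- validate_ptms(ptms, alignment)
  }
  if (is.character(regions)) {
    input_paths <- c(input_paths, regions)
    regions <- read_regions(regions, alignment)
  }

  interfaces <- NULL
  chain <- NULL
  mapping <- NULL
  if (!is.null(structure_path)) {
    input_paths <- c(input_paths, structure_path)
    if (is.null(structure_protein)) {
      warn("structure given without structure_protein; skipping interface stage")
    } else {
      chain <- read_structure(structure_path, chain_a)
      partner <- read_structure(structure_path, chain_b)
      iface <- detect_interface(chain, partner,
                                cutoff = config$interface_cutoff,
                                protein_a = structure_protein,
                                protein_b = chain_b)
      mapping <- map_structure_to_alignment(chain, alignment,
                                            structure_protein)
      # interface residue numbers are chain numbering; translate to the
      # member's native coordinates through the chain mapping
      nat <- mapping$native_pos[match(iface$a$native_pos, mapping$resno)]
      interfaces <- tibble(
        protein_id = structure_protein,
        native_pos = nat[!is.na(nat)]
      )
    }
  }

  if (nrow(ptms) == 0L) {
    warn("empty PTM table: producing empty feature and rank tables")
  }
  maps <- build_maps(ptms, alignment)
  features <- compute_features(maps, alignment, interfaces = interfaces,
                               window = config$window,
                               scope = config$conservation_scope)
  scores <- score_maps(features, w1 = config$w1, w2 = config$w2,
                       nkc_mode = config$nkc_mode, n_bins = config$n_bins)

  enrich <- NULL
  if (!is.null(regions)) {
    scope_regions <- NULL
    cyto <- regions[regions$scope == "native" &
                      grepl("cytoplasmic", regions$name, ignore.case = TRUE), ]
    if (nrow(cyto)) {
      scope_regions <- cyto[, c("protein_id", "start", "end")]
    }
    enrich <- enrichment_table(
      ptms, alignment,
      regions[!grepl("cytoplasmic", regions$name, ignore.case = TRUE), ],
      residues = config$acceptor_residues, scope_regions = scope_regions
    )
  } else {
    warn("no region annotations: skipping enrichment stage")
  }

  crosstalk <- crosstalk_pairs(ptms, window = config$crosstalk_window)

  projected_path <- NULL
  if (!is.null(chain) && !is.null(mapping) && !is.null(out_dir)) {
    projected_path <- file.path(out_dir, "projected.pdb")
  }

  manifest <- list(
    config = unclass(config),
    inputs = as.list(tools::md5sum(input_paths[file.exists(input_paths)])),
    n_sequences = nrow(alignment),
    n_columns = n_columns(alignment),
    n_ptms = nrow(ptms),
    n_maps = nrow(maps),
    package_version = as.character(utils::packageVersion("ptmhotspots"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(features, file.path(out_dir, "features.tsv"))
    rank_tbl <- tidy(scores)[, c("rank", "column", "is", "bin", "pc", "cpc",
                                 "prc", "nkc", "ppi", "member_ptms")]
    readr::write_tsv(rank_tbl, file.path(out_dir, "ranks.tsv"))
    if (!is.null(enrich)) {
      readr::write_tsv(enrich, file.path(out_dir, "enrichment.tsv"))
    }
    readr::write_tsv(crosstalk, file.path(out_dir, "crosstalk.tsv"))
    if (!is.null(projected_path)) {
      project_scores(chain, mapping, scores, projected_path)
      manifest$projected <- "projected.pdb"
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(
    alignment = alignment, maps = maps, features = features,
    scores = scores, enrichment = enrich, crosstalk = crosstalk,
    interfaces = interfaces, mapping = mapping, manifest = manifest
  )
}
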