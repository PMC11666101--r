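# End-to-end pipeline: scan -> align -> conserve -> variants -> graft ->
# sample -> occlusion/pore -> verdicts, with a layered configuration whose
# serialized copy is embedded in every output bundle.

#' Default pipeline configuration
#'
#' Every pinned parameter, with a provenance tag: `"protocol"` for values
#' taken from the reference analysis protocol (snapshot count, pull
#' velocity/spring constant, linker contour), `"default"` for artifact
#' decisions (cutoffs, thresholds, seeds).
#'
#' @param ... Named overrides of the defaults (unknown keys are rejected).
#' @return A `glycoshield_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    substitution_rate = 0.06,
    family_seed = 101L,
    resolved_only = TRUE,
    contact_cutoff = 4.5,
    interface_cutoff = 5.0,
    voxel = 1.0,
    frame_threshold = 0.5,
    blocked_at = 0.8,
    accessible_at = 0.2,
    clash_cutoff = 2.4,
    move_width = 30,
    temperature = 0.5,
    n_frames = 30L,
    steps_per_frame = 15L,
    max_attempts = 20000L,
    pore_radius = 6,
    pore_length = 30,
    linker_residues = 15L,
    pull_velocity = 5,
    pull_spring_constant = 100,
    provenance = c(
      n_frames = "protocol", pull_velocity = "protocol",
      pull_spring_constant = "protocol", linker_residues = "default",
      contact_cutoff = "default", interface_cutoff = "default",
      voxel = "default", frame_threshold = "default",
      blocked_at = "default", accessible_at = "default",
      clash_cutoff = "default", pore_radius = "default",
      pore_length = "default"
    )
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  class(cfg) <- "glycoshield_config"
  cfg
}

#' Run the toy-scale analysis pipeline
#'
#' Executes the full chain on the synthetic study system: sequon scan and
#' conservation mapping over the synthetic NaV family, the clinical variant
#' report, glycan grafting and ensemble sampling on the toy channel,
#' occupancy, pore check and occlusion verdict against the toy complex
#' footprint, and the trans-bridge distances for both dimer modes. Returns
#' one bundle (and optionally writes JSON + CSVs).
#'
#' @param config A [default_config()].
#' @param outdir Optional output directory for the report bundle
#'   (`bundle.json`, `conservation.csv`, `variants.csv`).
#' @return A named list bundle; every numeric traces to a config parameter or
#'   a computed value, and the config is embedded under `$config`.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL) {
  stopifnot(inherits(config, "glycoshield_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
  }

  fam <- stage("family", synthetic_nav_family(
    seed = config$family_seed, substitution_rate = config$substitution_rate
  ))
  sequons <- stage("scan", do.call(rbind, lapply(fam$sequences, scan_sequons)))
  aln <- stage("align", align_isoforms(fam$sequences))
  cmap <- stage("conserve", map_conserved_sequons(
    aln, sequons,
    resolved = fam$resolved, resolved_only = config$resolved_only
  ))
  tabs <- stage("tables", load_paper_tables())
  vrep <- stage("variants", build_variant_report(fam$sequences, tabs$variants))

  toy <- stage("toy_channel", make_toy_channel())
  tree <- tabs$glycan_tree
  sp <- sampler_params(
    n_frames = config$n_frames, move_width = config$move_width,
    temperature = config$temperature, clash_cutoff = config$clash_cutoff,
    seed = config$seed, max_attempts = config$max_attempts,
    steps_per_frame = config$steps_per_frame
  )
  grafts <- stage("graft", lapply(
    attr(toy, "glycosites"),
    function(rn) graft_glycan(toy, "A", rn, tree, params = sp)
  ))
  ens <- stage("sample", sample_ensemble(toy, grafts, params = sp))
  grid <- stage("grid", build_grid(ens, voxel = config$voxel))
  pore <- stage("pore", pore_block_check(
    ens, attr(toy, "pore_point"), attr(toy, "pore_axis"),
    radius = config$pore_radius, length = config$pore_length
  ))

  cx <- stage("toy_complex", make_toy_complex())
  fp <- stage("interface", extract_interface(
    cx, "A", "B",
    cutoff = config$interface_cutoff, partner_label = "beta1"
  ))
  occ <- stage("occlusion", occlusion_score(
    ens, cx, "A", fp$residues,
    contact_cutoff = config$contact_cutoff,
    frame_threshold = config$frame_threshold,
    blocked_at = config$blocked_at, accessible_at = config$accessible_at,
    region = "beta1_footprint"
  ))
  verdicts <- stage("verdict", binding_verdict(list(beta1 = occ)))

  ig <- stage("toy_ig", make_toy_ig())
  dim_tip <- stage("bridge_tip", build_dimer(
    ig,
    mode = "tip", linker_residues = config$linker_residues
  ))
  dim_side <- stage("bridge_side", build_dimer(
    ig,
    mode = "side", linker_residues = config$linker_residues
  ))
  pull <- stage("pull", coarse_pull(
    dim_tip,
    pull_params(
      velocity = config$pull_velocity,
      spring_constant = config$pull_spring_constant
    ),
    seed = config$seed
  ))

  summary_counts <- conservation_summary(cmap)
  bundle <- list(
    config = unclass(config),
    conservation = cmap,
    conservation_groups = summary_counts,
    n_all_isoform_groups = sum(summary_counts$class == "all"),
    variant_report = vrep,
    disrupting_counts = as.list(attr(vrep, "disrupting_counts")),
    ensemble = list(
      n_frames = length(ens$frames), status = ens$status,
      acceptance_rate = ens$params$acceptance_rate
    ),
    grid = list(
      dim = grid$dim, voxel = grid$voxel,
      occupied_voxels = sum(grid$occupancy > 0)
    ),
    pore_blocked_fraction = pore,
    occlusion = list(
      region = occ$region, coverage = occ$coverage,
      mean_contact_fraction = occ$mean_contact_fraction,
      verdict = occ$verdict
    ),
    verdicts = verdicts,
    bridge = list(
      tip_nm = max_extension_distance(dim_tip),
      side_nm = max_extension_distance(dim_side),
      pull_status = pull$status,
      rupture_distance_nm = pull$rupture_distance_nm,
      reported_distance_nm = pull$reported_distance_nm
    )
  )
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      bundle[setdiff(names(bundle), c("conservation", "variant_report"))],
      file.path(outdir, "bundle.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE
    )
    write_conservation_csv(cmap, file.path(outdir, "conservation.csv"))
    write.csv(vrep, file.path(outdir, "variants.csv"), row.names = FALSE)
  }
  bundle
}
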