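# End-to-end orchestration of the bottom-up path on a phantom: stacking,
# stack2ex, ex2in, stack2in, evaluation, and the run manifest.

# VOI masks on the reconstructed stack grid: per-section truth labels
# resampled with the recovered per-slice transforms
stack_voi_masks <- function(phantom, stackres) {
  n <- length(phantom$section_labels)
  d <- dim(phantom$section_labels[[1]])
  lab <- array(0L, c(d, n))
  for (k in seq_len(n))
    lab[, , k] <- round(resample_2d(phantom$section_labels[[k]],
                                    stackres$per_slice_transforms[[k]],
                                    stackres$pixel_size, scheme = 0L, fill = 0))
  list(viable = lab == 1L, necrotic = lab == 2L, hemorrhagic = lab == 3L)
}

# label volume resampled (nearest) onto a realigned grid
labels_on_grid <- function(labels, src_vol, ref_vol) {
  lv <- volume_image(labels * 1.0, spacing = src_vol$spacing,
                     origin = src_vol$origin, direction = src_vol$direction)
  round(resample(lv, NULL, ref_vol, scheme = "nearest")$values)
}

#' Summary table of a full pipeline run
#'
#' Per registration level: landmark RMS through the concatenated stack2in
#' transform, out-of-plane angulation and global Jacobian volume change per
#' stage, and per-VOI volume changes through the full stage composites --
#' the quantitative evaluation of the methodology.
#'
#' @param s2e,e2i stage results.
#' @param lm_invivo,lm_stack corresponding landmark sets in the in vivo
#'   world frame and the stack frame.
#' @param plane the reference plane (for the ex2in angulation normal).
#' @param voi_stack,voi_ex optional named lists of VOI masks on the stack /
#'   ex vivo grids (for per-VOI volume changes).
#' @param t_initial optional pre-registration correspondence
#'   (\code{\link{plane_identification}}).
#' @param stack_vol,ex_vol,invivo_vol the corresponding grids.
#' @return list with \code{rms} (named vector), \code{table} (data.frame),
#'   and \code{voi} (per-stage, per-VOI percent changes).
#' @export
evaluation_summary <- function(s2e, e2i, lm_invivo, lm_stack, plane = NULL,
                               voi_stack = NULL, voi_ex = NULL,
                               stack_vol = NULL, ex_vol = NULL,
                               invivo_vol = NULL, t_initial = NULL) {
  rms <- stagewise_landmark_rms(s2e, e2i, lm_invivo, lm_stack, t_initial)
  n_e2i <- if (!is.null(plane)) plane$normal else c(0, 0, 1)
  tab <- data.frame(
    step = c("stack2ex", "ex2in"),
    dV_global_percent = c(global_volume_change(s2e),
                          global_volume_change(e2i)),
    angulation_deg = c(angulation_report(s2e, c(0, 0, 1)),
                       angulation_report(e2i, n_e2i)))
  voi <- list()
  if (!is.null(voi_stack) && !is.null(stack_vol) && !is.null(ex_vol))
    voi$stack2ex <- voi_volume_changes(s2e, voi_stack, stack_vol, ex_vol)
  if (!is.null(voi_ex) && !is.null(ex_vol) && !is.null(invivo_vol))
    voi$ex2in <- voi_volume_changes(e2i, voi_ex, ex_vol, invivo_vol)
  list(rms = rms, table = tab, voi = voi)
}

#' Run the complete bottom-up pipeline on a synthetic phantom
#'
#' Generates (or takes) a phantom, stacks its sections, registers the stack
#' to the ex vivo MRI and the ex vivo to the realigned in vivo MRI,
#' concatenates the transforms, warps the color stack onto the in vivo
#' grid, and evaluates landmark RMS, angulation and volume changes. All
#' outputs (volumes, transform files, metric logs, evaluation CSV, run
#' manifest) are written under \code{out_dir}. Fully reproducible for a
#' fixed seed: re-running with the manifest's seed yields byte-identical
#' transform files.
#'
#' @param out_dir output directory (created).
#' @param seed integer seed driving the phantom and all registrations.
#' @param cfg optional named list of configuration sections
#'   (\code{phantom}, \code{stack}, \code{stack2ex}, \code{ex2in}) with
#'   overrides for \code{\link{phantom_config}} /
#'   \code{\link{registration_config}} fields.
#' @param phantom optionally, a pre-generated \code{tumor_phantom} (its
#'   seed takes precedence).
#' @return (invisibly) a list with the phantom, stage results, warped
#'   stack, evaluation and manifest.
#' @export
run_all <- function(out_dir, seed = 1, cfg = list(), phantom = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tdir <- file.path(out_dir, "transforms")
  dir.create(tdir, showWarnings = FALSE)

  if (is.null(phantom)) {
    pargs <- modifyList(list(seed = seed), cfg$phantom %||% list())
    phantom <- generate_phantom(do.call(phantom_config, pargs))
  }
  seed <- phantom$cfg$seed

  # 1. stacking
  stackres <- stack_sections(phantom$sections,
                             stage_registration_config(
                               cfg, "stack", seed = seed,
                               metric = "normalized_correlation"))
  stack_vol <- stackres$channels[[stackres$driver_channel]]

  # 2. realign the ex vivo volume so the reference plane is slice 0
  ex_re <- realign_to_reference_plane(phantom$exvivo, phantom$plane_exvivo)
  lab_ex_re <- labels_on_grid(phantom$labels_exvivo, phantom$exvivo, ex_re)

  # 3. stack2ex: histology stack (moving) to ex vivo MRI (fixed)
  zmax <- (dim(stack_vol$values)[3] - 1) * stack_vol$spacing[3]
  zw <- grid_world_points(ex_re)[, 3]
  slab <- array(zw >= ex_re$origin[3] - 1e-9 &
                  zw <= ex_re$origin[3] + zmax + 1e-9, dim(ex_re$values))
  cfg_s2e <- stage_registration_config(cfg, "stack2ex", seed = seed + 10L)
  cfg_s2e$fixed_mask <- mask_dilate(lab_ex_re > 0, 3) & slab
  s2e <- stack2ex(stackres, ex_re, cfg_s2e)

  # 4. ex2in: ex vivo (moving) to realigned in vivo (fixed)
  cfg_e2i <- stage_registration_config(cfg, "ex2in", seed = seed + 20L)
  in_re <- realign_to_reference_plane(phantom$invivo, phantom$plane,
                                      out_spacing = ex_re$spacing)
  cfg_e2i$fixed_mask <- mask_dilate(labels_on_grid(phantom$labels_invivo,
                                                   phantom$invivo,
                                                   in_re) > 0, 3)
  e2i <- ex2in(ex_re, in_re, plane = NULL, cfg = cfg_e2i)
  e2i$fixed_realigned <- in_re

  # 5. concatenation and color warp
  s2i <- stack2in(s2e, e2i, stackres, invivo_grid = in_re)

  # 6. evaluation
  voi_stack <- stack_voi_masks(phantom, stackres)
  voi_ex <- lapply(c(viable = 1L, necrotic = 2L, hemorrhagic = 3L),
                   function(l) lab_ex_re == l)
  t_init <- plane_identification(in_re, stack_vol)
  ev <- evaluation_summary(s2e, e2i, phantom$landmarks_invivo,
                           phantom$landmarks_stack, plane = phantom$plane,
                           voi_stack = voi_stack, voi_ex = voi_ex,
                           stack_vol = stack_vol, ex_vol = ex_re,
                           invivo_vol = in_re, t_initial = t_init)

  # 7. outputs
  write_volume(phantom$invivo, file.path(out_dir, "invivo.mha"))
  write_volume(phantom$exvivo, file.path(out_dir, "exvivo.mha"))
  for (ch in names(s2i$volume))
    write_volume(s2i$volume[[ch]],
                 file.path(out_dir, sprintf("stack2in_%s.mha", ch)))
  tr_paths <- c(
    vapply(seq_along(stackres$per_slice_transforms), function(i) {
      write_transform(stackres$per_slice_transforms[[i]],
                      file.path(tdir, sprintf("stack_slice_%03d.txt", i)))
    }, ""),
    stack2ex_rigid = write_transform(s2e$rigid, file.path(tdir, "stack2ex_rigid.txt")),
    stack2ex_affine = write_transform(s2e$affine, file.path(tdir, "stack2ex_affine.txt")),
    stack2ex_elastic = write_transform(s2e$composite, file.path(tdir, "stack2ex_composite.txt")),
    ex2in_rigid = write_transform(e2i$rigid, file.path(tdir, "ex2in_rigid.txt")),
    ex2in_similarity = write_transform(e2i$affine, file.path(tdir, "ex2in_similarity.txt")),
    ex2in_elastic = write_transform(e2i$composite, file.path(tdir, "ex2in_composite.txt")),
    stack2in = write_transform(s2i$transform, file.path(tdir, "stack2in_composite.txt")))
  write_landmarks(phantom$landmarks_invivo,
                  file.path(out_dir, "landmarks_invivo.txt"))
  write_landmarks(phantom$landmarks_stack,
                  file.path(out_dir, "landmarks_stack.txt"))

  metrics_df <- rbind(
    data.frame(stage = "stack2ex", level = names(s2e$metrics),
               metric = unname(s2e$metrics)),
    data.frame(stage = "ex2in", level = names(e2i$metrics),
               metric = unname(e2i$metrics)))
  write.csv(metrics_df, file.path(out_dir, "metric_log.csv"),
            row.names = FALSE)
  eval_df <- data.frame(level = names(ev$rms), landmark_rms_mm = unname(ev$rms))
  write.csv(eval_df, file.path(out_dir, "landmark_rms.csv"), row.names = FALSE)
  write.csv(ev$table, file.path(out_dir, "stage_summary.csv"),
            row.names = FALSE)
  if (length(ev$voi)) {
    voi_df <- do.call(rbind, lapply(names(ev$voi), function(s)
      data.frame(step = s, voi = names(ev$voi[[s]]),
                 dV_percent = unname(ev$voi[[s]]))))
    write.csv(voi_df, file.path(out_dir, "voi_volume_change.csv"),
              row.names = FALSE)
  }

  manifest <- list(
    tool = "histomri",
    version = as.character(utils::packageVersion("histomri")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = cfg,
    phantom_config = unclass(phantom$cfg),
    transforms = as.list(tr_paths),
    input_digests = as.list(tools::md5sum(
      file.path(out_dir, c("invivo.mha", "exvivo.mha")))),
    summary = list(landmark_rms = as.list(ev$rms),
                   dV_global = as.list(setNames(ev$table$dV_global_percent,
                                                ev$table$step)),
                   angulation_deg = as.list(setNames(ev$table$angulation_deg,
                                                     ev$table$step))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(phantom = phantom, stack = stackres, s2e = s2e, e2i = e2i,
                 s2i = s2i, evaluation = ev, manifest = manifest,
                 ex_realigned = ex_re, invivo_realigned = in_re))
}
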