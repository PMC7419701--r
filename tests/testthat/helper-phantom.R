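# Shared desk-side fixtures: small phantoms kept cheap enough for unit tests.

tiny_atlas <- function(grid = c(16, 16, 16), n_networks = 3,
                       rois_per_network = 2, seed = 1) {
  make_phantom_atlas(grid, n_networks, rois_per_network, seed = seed)
}

tiny_protocol <- function(n_frames = 60, grid = c(16, 16, 16), tr = 2.2,
                          n_runs = 1) {
  acquisition_protocol(tr, n_frames, n_runs, 3, grid)
}

# a bold_run with externally supplied frame x voxel data on a tiny grid
manual_run <- function(mat, grid = c(16, 16, 16), tr = 2.2,
                       brain_mask = NULL) {
  proto <- acquisition_protocol(tr, nrow(mat), 1, 3, grid)
  structure(list(data = array(t(mat), dim = c(grid, nrow(mat))),
                 protocol = proto,
                 brain_mask = brain_mask %||% array(TRUE, grid),
                 motion_spike_frames = integer(0),
                 wm_mask = NULL, csf_mask = NULL),
            class = "bold_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_matrix <- function(run) {
  d <- dim(run$data)
  t(matrix(run$data, nrow = prod(d[1:3]), ncol = d[4]))
}

cohort_fixture_path <- function() {
  system.file("extdata", "cohort_table1.tsv", package = "langmap")
}
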