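# a small but complete study configuration used by the pipeline tests
demo_config <- function(out_dir, seed = 1) {
  list(
    version = 1,
    seed = seed,
    output_dir = out_dir,
    simulate = list(
      mycelium = list(
        list(name = "sparse_2dpi", medium = "PDB_1_10", timepoint = 2, n_images = 2,
             params = list(branch_prob = 0.02, width_px = 192,
                           height_px = 192, n_steps = 55)),
        list(name = "dense_2dpi", medium = "PDB", timepoint = 2, n_images = 2,
             params = list(branch_prob = 0.12, width_px = 192,
                           height_px = 192, n_steps = 55)),
        list(name = "sparse_8dpi", medium = "PDB_1_10", timepoint = 8, n_images = 2,
             params = list(branch_prob = 0.04, width_px = 192,
                           height_px = 192, n_steps = 55)),
        list(name = "dense_8dpi", medium = "PDB", timepoint = 8, n_images = 2,
             params = list(branch_prob = 0.15, width_px = 192,
                           height_px = 192, n_steps = 55))
      ),
      drops = list(
        list(name = "flower", medium = list("PDB", "PDB", "PDB_1_2",
                                            "PDB_1_2", "PDB_1_10", "PDB_1_10"),
             width_px = 600, height_px = 200,
             drops = list(
               list(cx = 50, cy = 50, r = 40, red_fraction = 0.75),
               list(cx = 150, cy = 50, r = 40, red_fraction = 0.70),
               list(cx = 250, cy = 50, r = 40, red_fraction = 0.50),
               list(cx = 350, cy = 50, r = 40, red_fraction = 0.45),
               list(cx = 450, cy = 50, r = 40, red_fraction = 0.10),
               list(cx = 550, cy = 50, r = 40, red_fraction = 0.12)))
      ),
      fractals = list(
        list(name = "carpet4", kind = "sierpinski_carpet", level = 4)
      )
    ),
    fd = list(sizes = c(3, 6, 12, 24, 48, 96, 192)),
    colour = list(min_particle_px = 0),
    stats = list()
  )
}
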