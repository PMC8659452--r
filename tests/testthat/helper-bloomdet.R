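# shared fixtures built in code

# a small deterministic scene for io/augment tests
small_scene <- function(seed = 5L, size = 160L) {
  cfg <- scene_config(width = size, height = size, n_flowers = 2, n_buds = 1,
                      flower_size_range = c(40, 60), bud_size_range = c(16, 24),
                      occlusion_prob = 0, background = "simple", seed = seed)
  generate_scene(cfg)
}

flat_image <- function(value = 255, size = 64L, boxes = NULL) {
  labeled_image("flat", pixels = array(value, dim = c(size, size, 3)),
                boxes = boxes %||% bloomdet:::empty_boxes())
}

# hand-written LabelImg-style VOC XML fixture
write_voc_fixture <- function(path, objects = TRUE) {
  lines <- c(
    "<annotation>",
    "  <folder>images</folder>",
    "  <filename>fixture.png</filename>",
    "  <size><width>100</width><height>200</height><depth>3</depth></size>",
    if (objects) c(
      "  <object>",
      "    <name>bud</name>",
      "    <bndbox><xmin>10</xmin><ymin>10</ymin><xmax>30</xmax><ymax>40</ymax></bndbox>",
      "  </object>"
    ),
    "</annotation>"
  )
  writeLines(lines, path)
  path
}

`%||%` <- rlang::`%||%`
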