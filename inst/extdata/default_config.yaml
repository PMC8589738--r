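# Default ctbiopsim configuration (all values shown equal the built-in
# defaults; any key may be omitted).
seed: 1
log_level: info
hit_tolerance_mm: 0
phantom:
  shape: [128, 128, 96]
  spacing: [3, 3, 3]
  body_semi_axes: [170, 120]
  noise_sd: 10
  hu: {air: -1000, fat: -90, soft_tissue: 40, bone: 700, blood: 200}
  lesions:
    - {name: pararenal node, centroid: [70, 20, 0], radius: 8, difficulty: beginner, hu: 60}
    - {name: para-aortic node, centroid: [27, 35, 0], radius: 6, difficulty: expert, hu: 60}
scan:
  slice_thickness: 3
  slice_spacing: 3
  in_plane_pixel_size: 1
  needle_hu: 3071
  supersampling: 3
needle_board: {squares_x: 5, squares_y: 7, square_size: 10}
reference_board: {squares_x: 8, squares_y: 10, square_size: 15}
camera: {fx: 1400, fy: 1400, cx: 960, cy: 540, width: 1920, height: 1080}
needle: {shaft_length: 150, shaft_diameter: 3}
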