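Package: branchrecon
Title: Branch Reconstruction from Instance Masks by Bidirectional Sector Search
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reconstructs complete vine-like plant branches from the fragmented
    instance-segmentation masks produced by detection models. Each detected
    branch fragment is reduced to its minimum-area oriented bounding rectangle
    and a three-point long-axis model; fragments are then grouped by a greedy
    bidirectional sector search that grows each branch from both ends, attaches
    bifurcation (fork) instances, joins chains split at forks or by missed
    detections in a secondary connection pass, and prunes isolated spurious
    fragments. Includes reconstruction quality metrics (reconstruction
    accuracy, mean mask IoU, diameter errors, detection precision/recall/F1),
    a seeded synthetic vine-scene generator with ground truth for end-to-end
    validation, readers and writers for per-instance PNG masks and COCO-style
    polygon annotations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    stats,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
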