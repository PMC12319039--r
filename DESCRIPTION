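Package: podmatch
Title: Cross-View Soybean Pod Classification and Counting with Siamese
    Similarity Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Counts one- to four-seed soybean pods on intact plants
    photographed from two sides. Per-view pod detections are cropped,
    compared across views with a squeeze-and-excitation Siamese similarity
    network, deduplicated by greedy threshold matching, and tallied per pod
    class. Includes a paired-scene synthetic data generator with known pod
    identity and occlusion, readers and writers for COCO-style JSON and
    flat CSV detection files, the standard augmentation pipeline
    (mirroring, salt-and-pepper noise, 180-degree rotation), and a full
    evaluation suite: IoU-based true-positive assignment, precision,
    recall, F1, average precision and mAP, count-regression errors (MAE,
    RMSE, coefficient of determination) and per-category count accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
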