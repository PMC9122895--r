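# Reference configuration of the YOLOv4-style one-stage detector that the
# package's simulated detector stands in for. This file documents the
# architecture and training recipe for users who want to train the real
# network with Darknet; nothing in wormcensus instantiates it.

input:
  width: 704
  height: 528
  channels: 1          # background-corrected grayscale (Image D)

backbone:
  name: CSPDarknet53   # Darknet53 (52 conv layers) with cross-stage-partial blocks
  activation: mish
  csp_block_repeats: [1, 2, 8, 8, 4]

neck:
  spp_pool_sizes: [5, 9, 13]   # spatial pyramid pooling filter sizes (px)
  aggregation: PAN             # path aggregation network over scales S1-S3
  activation: leaky_relu

head:
  type: YOLOv3                 # one-stage, anchor-based
  anchors_per_scale: 3
  # filters of the conv layer before each YOLO layer: (classes + 5) * 3
  filters:
    occ: 18                    # 1 class
    mcc: 27                    # 4 classes

classes:
  occ: [worm]
  mcc: [worm_x1, worm_x2, worm_x3, worm_x4]

training:
  optimizer: sgd
  batch_size: 3
  iterations: 37000
  learning_rate: 0.001
  lr_decay: {factor: 0.8, every_steps: 50000}
  weight_decay: 0.0005
  momentum: 0.949
  loss: ciou

inference:
  confidence_threshold: 0.30
  nms_iou_threshold: 0.45
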