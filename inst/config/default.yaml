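# Reference-scale default configuration. Values mirror the published
# training recipe; desk-scale benchmarks override sizes via model_config()
# and train_schedule().
training:
  epochs: 100
  batch_size: 16
  lr_encoder: 3.0e-4
  lr_decoder: 1.0e-3
  warmup_epochs: 10
  eta_min: 1.0e-6
  weight_decay: 1.0e-2
  weight_decay_alt: 1.0e-4
  grad_clip: 1.0
sparse_attention:
  rho: 0.1
  tau0: 1.0
  tau_final: 0.1
moe:
  stage1_experts: 4
  stage2_experts: 3
  routing_k: 2
  gate_hidden: 512
  gate_temperature_stage1: 0.5
  gate_temperature_stage2: 0.3
  expert_dropout: 0.1
loss:
  lambda_seg: 1.0
  lambda1: 0.01
  lambda2: 0.001
  lambda2_alt: 0.002
augmentation:
  p_flip_h: 0.5
  p_flip_v: 0.5
  rotation_deg: 15
  rotation_deg_alt: 30
  scale_range: [0.8, 1.2]
  brightness_jitter: 0.2
  contrast_jitter: 0.2
  saturation_jitter: 0.1
  noise_sigma: 0.01
  p_noise: 0.3
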