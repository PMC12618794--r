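# Study-scale working-memory profile (overnight CPU job).
task: wm
N: 64
n_batch: 32
L_train: 2000
transient_train: 1000
L_eval: 2000
transient_eval: 1000
n_eval: 8
lambda_I: 0.1
lambda_reg: 0.0001
mm_iterations: 2000
sm_pretrain: 100
sm_per_mm: 20
lr_mm: 0.001
lr_sm: 0.001
sm_hidden: [128, 128]
sm_minibatch: 512
sigma_noise: 0.1
eval_every: 20
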