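{"version":1.3,"people":[{"pose_keypoints_2d":[0,0,0,46.981693783461708,60.196792140526583,0.94999999999999996,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,17.43430562166002,120.1967921405266,0.94999999999999996,14.07268528413862,118.57537938367247,0.94999999999999996,22.755094167485137,167.81576703428286,0.94999999999999996,4,212,0.94999999999999996,20.795925959181421,121.81820489738071,0.94999999999999996,38.714323436446435,168.49722622224081,0.94999999999999996,59.000000000000007,212,0.94999999999999996,0,0,0,0,0,0,0,0,0,0,0,0,81.627416997969533,220,0.94999999999999996,0,0,0,55.000000000000007,220,0.94999999999999996,26.627416997969522,220,0.94999999999999996,0,0,0,0,220,0.94999999999999996]}]}
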