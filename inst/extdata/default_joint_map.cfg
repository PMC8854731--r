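joint root = root_back_l root_back_r
joint torso = torso
joint neck = neck
joint head = head_front head_left head_right
joint hip_l = hip_l
joint hip_r = hip_r
joint knee_l = knee_l
joint knee_r = knee_r
joint ankle_l = ankle_l
joint ankle_r = ankle_r
joint toe_l = toe_l
joint toe_r = toe_r
joint shoulder_l = shoulder_l
joint shoulder_r = shoulder_r
joint elbow_l = elbow_l
joint elbow_r = elbow_r
joint wrist_l = wrist_l
joint wrist_r = wrist_r
joint finger_l = finger_l
joint finger_r = finger_r
root = root
left_hip = hip_l
right_hip = hip_r
group root = root
group torso = torso
group neck = neck
group head = head
group hip = hip_l hip_r
group knee = knee_l knee_r
group ankle = ankle_l ankle_r
group toe = toe_l toe_r
group shoulder = shoulder_l shoulder_r
group elbow = elbow_l elbow_r
group wrist = wrist_l wrist_r
group finger = finger_l finger_r
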