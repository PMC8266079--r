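protocol,mat_variable,canonical_field
*,time,time
*,com_pos,com_pos
*,com_vel,com_vel
*,q_ankle,ankle_angle
*,qd_ankle,ankle_vel
*,T_ankle,ankle_moment
*,emg_ta,emg_ta
*,emg_sol,emg_sol
*,emg_gas,emg_gas
*,Fy,grf_vertical
*,cop,cop_ap
*,subject_id,subject_id
*,mass,mass
*,l_max,com_height
*,condition,condition
*,speed,walking_speed
*,pert_onset,pert_onset
*,pert_direction,pert_direction
*,pert_magnitude,pert_magnitude
*,hs_left,hs_left
*,to_left,to_left
*,hs_right,hs_right
*,to_right,to_right
*,foot_heel,foot_heel
*,foot_toe,foot_toe
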