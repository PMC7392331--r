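item_id,label,budget_share_pct,budget_rank
health,Health,6.4,6
water_env,Water and Environment,4.6,10
education,Education,21.3,2
agriculture,Agriculture,6.1,7
works_transport,Works and Transport,22.1,1
social_dev,Social Development,1.5,11
security,Security,10,3
energy_mineral,Energy and Mineral Development,NA,NA
pub_sector_mgmt,Public Sector Management,NA,NA
accountability,Accountability,NA,NA
justice_law_order,"Justice, Law and Order",7.2,4
ict,Information and Communication Technology,0.3,16
lands_housing,"Lands, Housing and Urban Development",NA,NA
tourism_trade,"Tourism, Trade and Industry",NA,NA
pub_admin,Public Administration,NA,NA
legislature,Legislature,NA,NA
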