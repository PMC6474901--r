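protein	prominent_molpct	category
Dbfp1	G=26.6;Y=14.7;P=12.2;K=12.3	GY_rich
Dbfp7alpha	G=18.6;N=13.6;Y=10.2;Q=9.2;P=9.2	GY_rich
Dbfp9beta	G=37.8;Y=21.6;N=10.8	GY_rich
Dbfp15	G=30.8;Y=13.5;S=11.5	GY_rich
Dbfp2	P=25.0;Y=23.2;K=17.7;T=10.4	P_rich
Dbfp4	P=8.9;L=8.9;V=7.4	P_rich
Dbfp5	P=18.4;Y=11.1;G=11.1;Q=10.5	P_rich
Dbfp6	P=9.5;G=7.6;L=7.6;V=7.6	P_rich
Dbfp10alpha	P=18.2;D=15.9;Y=13.6;C=6.8	P_rich
Dbfp13alpha	P=15.9;R=12.2;T=12.2;Q=6.1	P_rich
Dbfp11gamma	C=15.7;P=13.0;D=10.3;Y=5.2	C_rich
Dbfp12delta	C=12.5;G=11.5;R=10.4;P=8.3	C_rich
Dbfp14gamma	R=18.4;C=16.3;P=12.0;G=10.2	C_rich
Dbfp16	C=13.6;W=13.6;P=6.8	C_rich
Dbfp17	C=15.0;K=15.0;G=10.0	C_rich
Dbfp8	S=22.7;K=12.0;G=11.3	uncategorized
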