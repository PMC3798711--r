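name	parent	macrohaplogroup	defining
H	NA	H	
U	H	U	m.5868T>A,m.14516C>T,m.12001A>G,m.2018C>T,m.11953G>A,m.10908T>C,m.12328C>T,m.6705C>T,m.7237C>T,m.10873G>A
U6	U	U	m.51A>G,m.10331C>T,m.9237A>G
J	H	J	m.10433A>T,m.10128G>A,m.5179G>A,m.9998A>G,m.15580C>T,m.10807C>T,m.15995C>T,m.15181T>C,m.412C>T,m.5993A>G,m.1339C>T,m.789G>A,m.5674T>C,m.10938A>G
M	H	M	m.14304G>C,m.3074A>T,m.9764C>T,m.10262C>T,m.13829T>C,m.826C>T,m.12228C>T,m.5056T>C,m.1723T>C,m.8646C>T,m.506T>C,m.4538C>T,m.1144T>C,m.11103T>C,m.5928A>G,m.11301C>T,m.10598A>G,m.5764T>C,m.3927C>T,m.10061C>T,m.11437C>T,m.12437C>T,m.393A>G,m.5968G>A,m.6055A>G,m.15490T>C,m.13202T>C,m.15476C>T,m.732A>G,m.11961A>G
L3	H	L3	m.6345C>G,m.10860C>T,m.10343A>G,m.11759C>T,m.1230C>T,m.15294A>G,m.16424A>G,m.12392G>A,m.9699A>G,m.3272G>A,m.13131C>T,m.6967C>T,m.14534C>T,m.16429T>C,m.12410C>T,m.13591G>A,m.12686A>G,m.2829C>T,m.2185C>T,m.2133A>G,m.5953T>C,m.12543T>C,m.8398T>C,m.11199C>T,m.4466A>G,m.8632G>A,m.7269C>T,m.13987T>C,m.14926C>T,m.15407G>A,m.5705C>T,m.1666C>T,m.1802G>A,m.13194C>T
L3e	L3	L3	m.11945T>A,m.2844T>C,m.8214C>T,m.7954C>T
L2	H	L2	m.7949T>G,m.9319C>T,m.13316C>T,m.9514A>G,m.3315C>T,m.14019A>G,m.254C>T,m.7863T>C,m.15077T>C,m.13863C>T,m.8857C>T,m.1207A>G,m.13322C>T,m.11123C>T,m.140T>C,m.13800G>A,m.10287T>C,m.9491A>G,m.568C>T,m.14100T>C,m.11306C>T,m.624T>C,m.14031A>G,m.1446C>T,m.6471G>A,m.13883A>G,m.6233T>C,m.4440A>G,m.11098T>C,m.15926G>A,m.1514A>G,m.15189A>G,m.8899C>T,m.9918C>T,m.16241T>C,m.3366A>G
L2a	L2	L2	m.10855C>G,m.8056T>C,m.9048T>C,m.2901A>G,m.8974G>A
L1	H	L1	m.5212T>G,m.2347G>A,m.7035C>T,m.600C>T,m.11308C>T,m.8352T>C,m.2709T>C,m.2385T>C,m.1066A>G,m.15908T>C,m.134G>A,m.9923A>G,m.15963T>C,m.4187C>T,m.10798G>A,m.14588C>T,m.12049T>C,m.5204A>G,m.3077A>G,m.9155A>G,m.12886C>T,m.12632T>C,m.3557C>T,m.14655C>T,m.11559C>T,m.9676G>A,m.6456A>G,m.10148T>C,m.1206G>A,m.15166A>G,m.4295T>C,m.589C>T,m.14505C>T,m.15693A>G,m.8707A>G,m.3862C>T,m.14666A>G,m.13821A>G
L1b	L1	L1	m.810A>G,m.16250A>G,m.9924A>G,m.5253C>T,m.13639A>G
L0	H	L0	m.561A>T,m.6298C>A,m.798A>G,m.9720G>A,m.16131C>T,m.15390T>C,m.5162A>G,m.2604G>A,m.6545A>G,m.13344A>G,m.4031T>C,m.16207C>T,m.7438C>T,m.2209C>T,m.7820A>G,m.3372C>T,m.10906C>T,m.7503C>T,m.906C>T,m.16329T>C,m.2903A>G,m.1648C>T,m.63C>T,m.11845G>A,m.4919G>A,m.10953G>A,m.14136G>A,m.7032C>T,m.14603A>G,m.14853G>A,m.211T>C,m.10725A>G,m.15393T>C,m.9419G>A,m.2658A>G,m.12276C>T,m.237C>T,m.8711A>G,m.15102T>C,m.7314T>C,m.5309G>A,m.11782A>G
L0a	L0	L0	m.14638C>T,m.13358T>C,m.6710A>G,m.3742A>G
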