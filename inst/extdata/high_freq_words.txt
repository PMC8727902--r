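time
year
people
way
day
man
thing
woman
life
child
world
school
state
family
student
group
country
problem
hand
part
place
case
week
company
system
program
question
work
government
number
night
point
home
water
room
mother
area
money
story
fact
month
lot
right
study
book
eye
job
word
business
issue
side
kind
head
house
service
friend
father
power
hour
game
line
end
member
law
car
city
community
name
president
team
minute
idea
kid
body
information
back
parent
face
others
level
office
door
health
person
art
war
history
party
result
change
morning
reason
research
girl
guy
moment
air
teacher
force
education
foot
boy
age
policy
process
music
market
sense
nation
plan
college
interest
death
experience
effect
use
class
control
care
field
development
role
effort
rate
heart
drug
show
leader
light
voice
wife
police
mind
price
report
decision
son
view
relationship
town
road
arm
difference
value
building
action
model
season
society
tax
director
position
player
record
paper
space
ground
form
event
official
matter
center
couple
site
project
activity
star
table
court
american
oil
situation
cost
industry
figure
street
image
phone
data
picture
practice
piece
land
product
doctor
wall
patient
worker
news
test
movie
north
love
support
technology
step
baby
computer
type
attention
film
tree
source
subject
rule
letter
answer
food
dog
plant
growth
direction
behavior
knowledge
truth
bed
summer
winter
spring
window
bird
bridge
river
garden
kitchen
coffee
salary
schedule
meeting
dinner
lunch
breakfast
train
station
ticket
travel
hotel
flight
airport
beach
ocean
mountain
forest
grass
flower
stone
glass
plate
spoon
knife
bottle
chair
desk
shelf
floor
ceiling
roof
engine
wheel
driver
passenger
journey
holiday
weekend
evening
afternoon
yesterday
tomorrow
weather
cloud
storm
snow
rain
wind
sun
moon
sky
fire
ice
metal
wood
cotton
leather
pocket
jacket
shirt
dress
shoe
hat
watch
clock
mirror
camera
radio
screen
message
signal
network
package
address
library
museum
theater
ticket
concert
artist
singer
dancer
writer
reader
speaker
listener
neighbor
visitor
guest
owner
manager
customer
seller
buyer
farmer
builder
painter
lawyer
nurse
soldier
captain
pilot
sailor
king
queen
prince
castle
village
island
valley
desert
cave
path
gate
fence
corner
middle
edge
surface
bottom
top
front
distance
weight
height
length
width
depth
speed
strength
energy
silence
noise
sound
smell
taste
touch
color
shape
size
pattern
design
style
fashion
beauty
nature
animal
horse
sheep
cow
chicken
fish
insect
spider
snake
lion
tiger
bear
wolf
fox
rabbit
mouse
monkey
elephant
whale
shark
eagle
branch
leaf
root
seed
fruit
apple
orange
banana
grape
lemon
potato
tomato
carrot
onion
bread
butter
cheese
milk
sugar
salt
pepper
honey
juice
tea
wine
meat
rice
soup
salad
cake
cookie
chocolate
candy
garden
farm
field
barn
harvest
season
autumn
nephew
uncle
aunt
cousin
sister
brother
daughter
husband
grandfather
grandmother
marriage
wedding
birthday
gift
present
surprise
secret
promise
dream
hope
fear
anger
joy
pride
shame
doubt
trust
faith
luck
chance
choice
freedom
justice
peace
danger
safety
risk
trouble
accident
damage
repair
tool
hammer
needle
thread
rope
chain
ladder
bucket
basket
box
bag
suitcase
envelope
stamp
pencil
brush
paint
ink
page
chapter
title
sentence
phrase
language
speech
accent
silence
laughter
smile
tear
breath
sleep
rest
exercise
walk
run
jump
climb
swim
dance
sing
play
read
write
draw
build
cook
clean
wash
drive
ride
fly
sail
visit
meet
talk
listen
watch
learn
teach
study
think
remember
forget
understand
explain
describe
compare
measure
count
collect
choose
decide
agree
refuse
accept
offer
share
borrow
lend
spend
save
earn
pay
sell
buy
trade
carry
lift
push
pull
throw
catch
hold
drop
open
close
lock
cover
fill
empty
pour
cut
break
fix
join
connect
separate
mix
stir
burn
freeze
melt
grow
plant
pick
gather
hunt
feed
protect
attack
defend
escape
hide
search
discover
explore
invent
create
destroy
finish
start
continue
stop
wait
hurry
arrive
leave
return
follow
lead
guide
help
serve
thank
welcome
invite
celebrate
enjoy
flexible
low
high
bright
dark
heavy
light
narrow
wide
deep
shallow
smooth
rough
sharp
soft
hard
warm
cool
fresh
clean
quiet
loud
early
late
quick
slow
strong
weak
young
old
new
large
small
long
short
tall
full
most
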